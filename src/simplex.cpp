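#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dense two-phase primal simplex with Bland's rule.
//
// Solves  max c'x  s.t.  Aub x <= bub,  Aeq x = beq,  x >= 0,
// with bub >= 0 and beq >= 0 required (all FBA constraints satisfy this).
// Bland's rule makes the solver deterministic and cycle-free, which the
// simulator relies on for seed-reproducibility of whole runs.

namespace {

const double EPS = 1e-9;
const double RATIO_EPS = 1e-10;

struct Tableau {
  int m;                 // constraint rows
  int ncols;             // structural + slack + artificial
  int nallowed;          // columns allowed to enter (excludes artificials in phase 2)
  std::vector<std::vector<double>> T; // m x (ncols + 1), last col = rhs
  std::vector<double> d;              // reduced-cost row, length ncols + 1
  std::vector<int> basis;             // basis[i] = column basic in row i
  std::vector<bool> active;           // redundant rows switched off
};

// One simplex run on the tableau (maximization; optimal when d_j >= -EPS).
// Returns 0 optimal, 1 unbounded, 2 iteration limit.
int simplex_iterate(Tableau &tb) {
  const int maxit = 20000;
  for (int it = 0; it < maxit; ++it) {
    int enter = -1;
    for (int j = 0; j < tb.nallowed; ++j) {
      if (tb.d[j] < -EPS) { enter = j; break; } // Bland: smallest index
    }
    if (enter < 0) return 0;
    int leave = -1;
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < tb.m; ++i) {
      if (!tb.active[i]) continue;
      double a = tb.T[i][enter];
      if (a > RATIO_EPS) {
        double ratio = tb.T[i][tb.ncols] / a;
        if (ratio < best - RATIO_EPS ||
            (ratio < best + RATIO_EPS && (leave < 0 || tb.basis[i] < tb.basis[leave]))) {
          best = ratio;
          leave = i;
        }
      }
    }
    if (leave < 0) return 1;
    // pivot on (leave, enter)
    double piv = tb.T[leave][enter];
    for (int j = 0; j <= tb.ncols; ++j) tb.T[leave][j] /= piv;
    for (int i = 0; i < tb.m; ++i) {
      if (i == leave) continue;
      double f = tb.T[i][enter];
      if (std::fabs(f) < 1e-14) continue;
      for (int j = 0; j <= tb.ncols; ++j) tb.T[i][j] -= f * tb.T[leave][j];
    }
    double fd = tb.d[enter];
    if (std::fabs(fd) > 0) {
      for (int j = 0; j <= tb.ncols; ++j) tb.d[j] -= fd * tb.T[leave][j];
    }
    tb.basis[leave] = enter;
  }
  return 2;
}

// status: 0 optimal, 1 infeasible, 2 unbounded, 3 numeric trouble
List lp_solve(const NumericVector &c,
              const NumericMatrix &Aub, const NumericVector &bub,
              const NumericMatrix &Aeq, const NumericVector &beq) {
  int n = c.size();
  int mub = bub.size();
  int meq = beq.size();
  int m = mub + meq;

  Tableau tb;
  tb.m = m;
  tb.ncols = n + mub + meq;
  tb.T.assign(m, std::vector<double>(tb.ncols + 1, 0.0));
  tb.basis.assign(m, 0);
  tb.active.assign(m, true);

  for (int i = 0; i < mub; ++i) {
    for (int j = 0; j < n; ++j) tb.T[i][j] = Aub(i, j);
    tb.T[i][n + i] = 1.0;            // slack
    tb.T[i][tb.ncols] = bub[i];
    tb.basis[i] = n + i;
  }
  for (int i = 0; i < meq; ++i) {
    int r = mub + i;
    for (int j = 0; j < n; ++j) tb.T[r][j] = Aeq(i, j);
    tb.T[r][n + mub + i] = 1.0;      // artificial
    tb.T[r][tb.ncols] = beq[i];
    tb.basis[r] = n + mub + i;
  }

  // Phase 1: maximize -(sum of artificials); d_j = z_j - c1_j
  tb.nallowed = tb.ncols;
  tb.d.assign(tb.ncols + 1, 0.0);
  for (int i = 0; i < meq; ++i) {
    int r = mub + i;
    for (int j = 0; j <= tb.ncols; ++j) tb.d[j] -= tb.T[r][j];
  }
  for (int i = 0; i < meq; ++i) tb.d[n + mub + i] += 1.0; // -c1_j for artificials
  int st = simplex_iterate(tb);
  if (st != 0) return List::create(_["status"] = 3);
  double phase1 = -tb.d[tb.ncols]; // objective value of phase 1 (<= 0)
  // d rhs holds z = c_B' b with our update scheme, objective = z; we stored
  // d as z_j - c_j and rhs as z. For phase 1, z = -(sum artificial values).
  if (tb.d[tb.ncols] < -1e-7) {
    return List::create(_["status"] = 1);
  }
  (void)phase1;

  // Drive remaining artificials out of the basis, or deactivate redundant rows.
  for (int i = 0; i < m; ++i) {
    if (!tb.active[i]) continue;
    if (tb.basis[i] >= n + mub) {
      int piv = -1;
      for (int j = 0; j < n + mub; ++j) {
        if (std::fabs(tb.T[i][j]) > EPS) { piv = j; break; }
      }
      if (piv < 0) { tb.active[i] = false; continue; }
      double p = tb.T[i][piv];
      for (int j = 0; j <= tb.ncols; ++j) tb.T[i][j] /= p;
      for (int k = 0; k < m; ++k) {
        if (k == i) continue;
        double f = tb.T[k][piv];
        if (std::fabs(f) < 1e-14) continue;
        for (int j = 0; j <= tb.ncols; ++j) tb.T[k][j] -= f * tb.T[i][j];
      }
      tb.basis[i] = piv;
    }
  }

  // Phase 2 objective.
  tb.nallowed = n + mub; // artificials may not re-enter
  tb.d.assign(tb.ncols + 1, 0.0);
  for (int j = 0; j < n; ++j) tb.d[j] = -c[j];
  for (int i = 0; i < m; ++i) {
    if (!tb.active[i]) continue;
    int b = tb.basis[i];
    double cb = (b < n) ? c[b] : 0.0;
    if (cb != 0.0) {
      for (int j = 0; j <= tb.ncols; ++j) tb.d[j] += cb * tb.T[i][j];
    }
  }
  st = simplex_iterate(tb);
  if (st == 1) return List::create(_["status"] = 2);
  if (st == 2) return List::create(_["status"] = 3);

  NumericVector x(n);
  for (int i = 0; i < m; ++i) {
    if (tb.active[i] && tb.basis[i] < n) x[tb.basis[i]] = tb.T[i][tb.ncols];
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".lp_simplex")]]
List lp_simplex(NumericVector c, NumericMatrix Aub, NumericVector bub,
                NumericMatrix Aeq, NumericVector beq) {
  return lp_solve(c, Aub, bub, Aeq, beq);
}

// Enzymatically constrained FBA solve.
//
// S      : metabolites x reactions stoichiometric matrix (steady-state rows)
// obj    : objective coefficients (usually an indicator of the ATP reaction)
// capsel : 0/1 per reaction, membership in the summed-flux constraint
// a      : enzymatic constraint (cap on summed flux), Inf to disable
// ub     : per-reaction upper bounds (Inf allowed)
// parsimonious: if true, a second LP minimizes total flux at the optimum so
//   degenerate optima resolve deterministically.
// [[Rcpp::export(name = ".fba_solve_cpp")]]
List fba_solve_cpp(NumericMatrix S, NumericVector obj, NumericVector capsel,
                   double a, NumericVector ub, bool parsimonious) {
  int n = obj.size();
  int m = S.nrow();

  bool capped = R_finite(a);
  std::vector<int> ubidx;
  for (int j = 0; j < n; ++j) {
    if (R_finite(ub[j])) ubidx.push_back(j);
  }
  int mub = (capped ? 1 : 0) + (int)ubidx.size();
  NumericMatrix Aub(mub, n);
  NumericVector bub(mub);
  int r = 0;
  if (capped) {
    for (int j = 0; j < n; ++j) Aub(r, j) = capsel[j];
    bub[r] = a;
    ++r;
  }
  for (size_t k = 0; k < ubidx.size(); ++k) {
    Aub(r, ubidx[k]) = 1.0;
    bub[r] = ub[ubidx[k]] < 0 ? 0.0 : ub[ubidx[k]];
    ++r;
  }
  NumericVector beq(m); // zeros
  List sol = lp_solve(obj, Aub, bub, S, beq);
  int status = sol["status"];
  if (status != 0) return List::create(_["status"] = status);
  double z = sol["objective"];
  if (z < 0) z = 0;

  if (!parsimonious) return sol;

  // Parsimonious step: fix c'x = z, minimize sum of fluxes.
  NumericMatrix Aeq2(m + 1, n);
  NumericVector beq2(m + 1);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) Aeq2(i, j) = S(i, j);
  for (int j = 0; j < n; ++j) Aeq2(m, j) = obj[j];
  beq2[m] = z;
  NumericVector c2(n);
  for (int j = 0; j < n; ++j) c2[j] = -1.0;
  List sol2 = lp_solve(c2, Aub, bub, Aeq2, beq2);
  int status2 = sol2["status"];
  if (status2 != 0) {
    // fall back to the primary solution rather than failing the step
    return sol;
  }
  return List::create(_["status"] = 0, _["x"] = sol2["x"], _["objective"] = z);
}
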