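#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Kawasaki-style conservative mixing of lattice-site contents.
//
// In random order, each site swaps its full content (a population id or
// emptiness) with a uniformly chosen Moore-neighbourhood site, provided
// neither partner has already swapped in this pass. Uses R's RNG so mixing
// is reproducible under set.seed().

namespace {

inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

void one_pass(IntegerMatrix &occ, double fraction) {
  int w = occ.nrow(), h = occ.ncol();
  int nsites = w * h;
  std::vector<int> order(nsites);
  for (int i = 0; i < nsites; ++i) order[i] = i;
  for (int i = nsites - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(order[i], order[j]);
  }
  std::vector<bool> swapped(nsites, false);
  int limit = (fraction >= 1.0) ? nsites : (int)(fraction * nsites + 0.5);
  int attempted = 0;
  for (int s = 0; s < nsites && attempted < limit; ++s) {
    int idx = order[s];
    if (swapped[idx]) continue;
    ++attempted;
    int x = idx % w, y = idx / w;
    int nbx[8], nby[8], k = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        if (dx == 0 && dy == 0) continue;
        int px = x + dx, py = y + dy;
        if (px < 0 || px >= w || py < 0 || py >= h) continue;
        nbx[k] = px; nby[k] = py; ++k;
      }
    }
    if (k == 0) continue;
    int pick = runif_int(k);
    int nidx = nby[pick] * w + nbx[pick];
    if (swapped[nidx]) continue;   // partner already swapped: no swap at all
    int tmp = occ(x, y);
    occ(x, y) = occ(nbx[pick], nby[pick]);
    occ(nbx[pick], nby[pick]) = tmp;
    swapped[idx] = true;
    swapped[nidx] = true;
  }
}

} // namespace

// [[Rcpp::export(name = ".kawasaki_pass_cpp")]]
IntegerMatrix kawasaki_pass_cpp(IntegerMatrix occ, int repeats, double fraction) {
  IntegerMatrix out = clone(occ);
  for (int r = 0; r < repeats; ++r) one_pass(out, fraction);
  return out;
}

// Mean-squared displacement of a lone population under the mixing scheme.
// Returns an n_steps x 2 matrix of (mean dx^2, mean dy^2) in lattice units,
// averaged over n_walks independent walks starting at (x0, y0) (0-based).
// [[Rcpp::export(name = ".kawasaki_msd_cpp")]]
NumericMatrix kawasaki_msd_cpp(int width, int height, int x0, int y0,
                               int n_steps, int n_walks, int repeats) {
  NumericMatrix msd(n_steps, 2);
  IntegerMatrix occ(width, height);
  for (int wlk = 0; wlk < n_walks; ++wlk) {
    std::fill(occ.begin(), occ.end(), 0);
    occ(x0, y0) = 1;
    int cx = x0, cy = y0;
    for (int t = 0; t < n_steps; ++t) {
      for (int r = 0; r < repeats; ++r) one_pass(occ, 1.0);
      if (occ(cx, cy) != 1) {
        // the walker moves at most `repeats` sites per step: search locally first
        bool found = false;
        for (int dx = -repeats; dx <= repeats && !found; ++dx) {
          for (int dy = -repeats; dy <= repeats && !found; ++dy) {
            int px = cx + dx, py = cy + dy;
            if (px < 0 || px >= width || py < 0 || py >= height) continue;
            if (occ(px, py) == 1) { cx = px; cy = py; found = true; }
          }
        }
        if (!found) {
          for (int i = 0; i < width * height; ++i) {
            if (occ[i] == 1) { cx = i % width; cy = i / width; break; }
          }
        }
      }
      double dx = cx - x0, dy = cy - y0;
      msd(t, 0) += dx * dx;
      msd(t, 1) += dy * dy;
    }
  }
  for (int t = 0; t < n_steps; ++t) {
    msd(t, 0) /= n_walks;
    msd(t, 1) /= n_walks;
  }
  return msd;
}
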