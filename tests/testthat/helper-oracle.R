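# Independent LP oracle: exhaustive vertex enumeration.
#
# Solves max c'x s.t. Aub x <= bub, Aeq x = beq, x >= 0 by enumerating all
# candidate active sets (equality rows plus n - m_eq choices among the
# inequality rows and nonnegativity bounds), solving each square system and
# keeping the best feasible solution. Exponential, for tiny LPs only; kept
# deliberately independent of the package's simplex.
lp_vertex_enumeration <- function(cc, Aub, bub, Aeq, beq, tol = 1e-9) {
  n <- length(cc)
  meq <- length(beq)
  # constraint pool: inequality rows and the bounds x_j >= 0 (as -x <= 0)
  pool_A <- rbind(Aub, -diag(n))
  pool_b <- c(bub, rep(0, n))
  npool <- nrow(pool_A)
  k <- n - meq
  if (k < 0) stop("overdetermined oracle problem")
  best <- -Inf
  best_x <- NULL
  combos <- if (k == 0) matrix(integer(0), nrow = 0, ncol = 1) else
    utils::combn(npool, k)
  ncol_c <- if (k == 0) 1 else ncol(combos)
  for (ci in seq_len(ncol_c)) {
    sel <- if (k == 0) integer(0) else combos[, ci]
    M <- rbind(Aeq, pool_A[sel, , drop = FALSE])
    rhs <- c(beq, pool_b[sel])
    if (qr(M)$rank < n) next
    x <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
    if (is.null(x)) next
    if (any(x < -tol)) next
    if (length(bub) && any(Aub %*% x > bub + tol)) next
    if (meq && any(abs(Aeq %*% x - beq) > 1e-7)) next
    v <- sum(cc * x)
    if (v > best + 1e-12) { best <- v; best_x <- x }
  }
  list(objective = best, x = best_x)
}

# Build the FBA constraint system of a gem exactly as the problem is posed
# (steady state, summed-flux cap, finite upper bounds), for handing to an
# independent solver.
fba_lp_matrices <- function(gem, a, env = c(), B_u = 1,
                            unlimited = character(),
                            constraint_scope = "all_but_objective") {
  rids <- gem$reactions$id
  n <- length(rids)
  S <- as.matrix(gem$S)
  capsel <- switch(constraint_scope,
    all_but_objective = as.numeric(rids != gem$objective),
    internal = as.numeric(!gem$reactions$is_exchange),
    all = rep(1, n))
  ub <- unname(gem$ub[rids])
  ex <- gem$exchange_index
  for (i in seq_len(nrow(ex))) {
    if (is.na(ex$uptake[i])) next
    j <- match(ex$uptake[i], rids)
    m <- ex$metabolite[i]
    b <- if (m %in% unlimited) Inf else {
      (if (m %in% names(env)) env[[m]] else 0) / B_u
    }
    ub[j] <- min(ub[j], b)
  }
  fin <- which(is.finite(ub))
  Aub <- rbind(matrix(capsel, nrow = 1),
               diag(n)[fin, , drop = FALSE])
  bub <- c(a, pmax(ub[fin], 0))
  list(cc = as.numeric(rids == gem$objective),
       Aub = Aub, bub = bub,
       Aeq = S, beq = rep(0, nrow(S)), rids = rids)
}

# a small library of toy model specs used by several test files
oracle_toy_specs <- function() {
  list(
    toy_gem_spec("chain1", list(
      list(substrate = "s", products = c(), n_reactions = 1, atp = 1))),
    toy_gem_spec("chain3", list(
      list(substrate = "s", products = c(p = 1), n_reactions = 3, atp = 2))),
    toy_gem_spec("branch", list(
      list(substrate = "s", products = c(), n_reactions = 2, atp = 4),
      list(substrate = "s", products = c(), n_reactions = 1, atp = 2))),
    toy_gem_spec("twosub", list(
      list(substrate = "s1", products = c(w = 2), n_reactions = 1, atp = 3),
      list(substrate = "s2", products = c(w = 1), n_reactions = 2, atp = 5))),
    toy_gem_spec("wide", list(
      list(substrate = "s", products = c(p = 1, q = 2), n_reactions = 2, atp = 6),
      list(substrate = "u", products = c(p = 1), n_reactions = 1, atp = 1)))
  )
}

toy_substrates <- function(spec) {
  paste0(unique(vapply(spec$pathways, `[[`, character(1), "substrate")), "(e)")
}
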