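# The enzymatically constrained FBA layer: uptake bounds, the LP solve
# against an exhaustive vertex-enumeration oracle, and growth conversion.

test_that("uptake bounds cap total uptake at site availability", {
  b <- uptake_bounds(c("lcts(e)" = 0.5), B_u = 2,
                     metabolites = c("lcts(e)", "lac(e)", "h2o(e)"))
  expect_equal(unname(b[["lcts(e)"]]), 0.25)  # total <= 0.5
  expect_equal(unname(b[["lac(e)"]]), 0)      # absent metabolite
  expect_equal(unname(b[["h2o(e)"]]), Inf)    # unlimited water
  expect_error(uptake_bounds(c("lcts(e)" = -1), 1), "negative")
})

test_that("hand-solved toy optima are reproduced exactly", {
  # chain: uptake + one ATP-producing reaction; cap a = 2 over both
  spec <- toy_gem_spec("chain1", list(
    list(substrate = "s", products = c(), n_reactions = 1, atp = 1)))
  gem <- make_toy_gem(spec)
  sol <- solve_fba(gem, c(), 1e10, a = 2, unlimited = "s(e)")
  expect_equal(unname(sol$fluxes[["EX_s(e)_rev"]]), 1, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[["PW1_R1"]]), 1, tolerance = 1e-9)
  expect_equal(sol$atp_flux, 1, tolerance = 1e-9)

  # no substrate: all fluxes zero
  sol0 <- solve_fba(gem, c(), 1e10, a = 2)
  expect_equal(sol0$status, "zero")
  expect_equal(sol0$atp_flux, 0)

  # branched: yield-per-flux 4/3 beats 1; all flux routed to the better path
  bspec <- toy_gem_spec("branch", list(
    list(substrate = "s", products = c(), n_reactions = 2, atp = 4),
    list(substrate = "s", products = c(), n_reactions = 1, atp = 2)))
  bgem <- make_toy_gem(bspec)
  bsol <- solve_fba(bgem, c(), 1e10, a = 3, unlimited = "s(e)")
  expect_equal(bsol$atp_flux, 4, tolerance = 1e-9)
  expect_equal(unname(bsol$fluxes[["PW2_R1"]]), 0)
})

test_that("solver matches exhaustive vertex enumeration on toy models", {
  for (spec in oracle_toy_specs()) {
    gem <- make_toy_gem(spec)
    subs <- toy_substrates(spec)
    for (a in c(0.5, 2, 7)) {
      sol <- solve_fba(gem, c(), 1e10, a = a, unlimited = subs)
      lp <- fba_lp_matrices(gem, a, unlimited = subs)
      oracle <- lp_vertex_enumeration(lp$cc, lp$Aub, lp$bub, lp$Aeq, lp$beq)
      expect_equal(sol$atp_flux, oracle$objective, tolerance = 1e-9,
                   label = paste0(spec$name, " a=", a))
      expect_equal(sol$atp_flux, toy_gem_optimum(spec, a), tolerance = 1e-9)
    }
  }
})

test_that("solver matches the oracle under finite availability", {
  set.seed(101)
  spec <- toy_gem_spec("twosub", list(
    list(substrate = "s1", products = c(w = 2), n_reactions = 1, atp = 3),
    list(substrate = "s2", products = c(w = 1), n_reactions = 2, atp = 5)))
  gem <- make_toy_gem(spec)
  for (rep in 1:10) {
    env <- c("s1(e)" = runif(1, 0, 2), "s2(e)" = runif(1, 0, 2))
    B <- 10^runif(1, 9, 10.5)
    a <- runif(1, 0.5, 4)
    sol <- solve_fba(gem, env, B, a = a)
    lp <- fba_lp_matrices(gem, a, env = env, B_u = B / 1e10)
    oracle <- lp_vertex_enumeration(lp$cc, lp$Aub, lp$bub, lp$Aeq, lp$beq)
    expect_equal(sol$atp_flux, oracle$objective, tolerance = 1e-8)
    # environmental mass safety: total uptake never exceeds availability
    up <- sol$uptake[names(sol$uptake) %in% names(env)]
    expect_true(all(up * B / 1e10 <= env[names(up)] + 1e-9))
    # anything drawn from outside the finite pools must be unlimited
    expect_identical(setdiff(names(sol$uptake)[sol$uptake > 1e-9],
                             c(names(env), "h2o(e)")), character(0))
  }
})

test_that("optimal ATP flux is monotone in the enzymatic constraint", {
  for (spec in oracle_toy_specs()[c(1, 3, 5)]) {
    gem <- make_toy_gem(spec)
    subs <- toy_substrates(spec)
    av <- seq(0.2, 5, length.out = 8)
    atp <- vapply(av, function(a) {
      solve_fba(gem, c(), 1e10, a = a, unlimited = subs)$atp_flux
    }, numeric(1))
    expect_true(all(diff(atp) >= -1e-9))
  }
})

test_that("per-unit fluxes are invariant under joint scaling of amounts and size", {
  spec <- oracle_toy_specs()[[4]]
  gem <- make_toy_gem(spec)
  env <- c("s1(e)" = 0.7, "s2(e)" = 0.2)
  s1 <- solve_fba(gem, env, 5e9, a = 2)
  s2 <- solve_fba(gem, 2 * env, 1e10, a = 2)
  expect_equal(s1$fluxes, s2$fluxes, tolerance = 1e-9)
})

test_that("steady state and the flux cap hold at the solution", {
  spec <- oracle_toy_specs()[[5]]
  gem <- make_toy_gem(spec)
  sol <- solve_fba(gem, c("s(e)" = 1, "u(e)" = 1), 1e10, a = 2)
  expect_lt(max(abs(as.matrix(gem$S) %*% sol$fluxes)), 1e-8)
  nonobj <- setdiff(names(sol$fluxes), gem$objective)
  expect_lte(sum(sol$fluxes[nonobj]), 2 + 1e-8)
  expect_true(all(sol$fluxes >= 0))
})

test_that("growth is linear in ATP production with Table-2 units", {
  expect_equal(growth_from_atp(1, 1e10), 1e9)
  expect_equal(growth_from_atp(0, 1e10), 0)
  expect_equal(growth_from_atp(0.5, 5e7), 2.5e6)
  expect_error(growth_from_atp(-1, 1e10))
})
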