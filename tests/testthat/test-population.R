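# Metapopulation dynamics: initialization, spreading, death, colonization,
# Kawasaki mixing, site exclusivity and cell bookkeeping.

small_setup <- function(width = 10, height = 4) {
  cons <- make_crossfeeding_consortium()
  roster <- community_roster(cons$gems)
  lat <- lattice_geometry("custom", width = width, height = height)
  list(cons = cons, roster = roster, lat = lat)
}

test_that("initialization occupies sites independently with one population each", {
  s <- small_setup(30, 6)
  set.seed(11)
  st <- initialize_community(s$roster, s$lat, p = 0.3, size = 5e7)
  expect_true(all(st$B == 5e7))
  expect_equal(anyDuplicated(cbind(st$col, st$row)), 0)
  expect_true(all(st$occ[cbind(st$col, st$row)] == seq_along(st$B)))

  one <- community_roster(s$cons$gems["producer"])
  st1 <- initialize_community(one, s$lat, p = 0.5)
  expect_true(all(one$species[st1$species] == "producer"))
})

test_that("metabolism couples the FBA solution to the site pools and growth", {
  spec <- toy_gem_spec("chain1", list(
    list(substrate = "s", products = c(p = 1), n_reactions = 1, atp = 2)))
  gem <- make_toy_gem(spec)
  roster <- community_roster(list(chain1 = gem))
  lat <- lattice_geometry("custom", width = 5, height = 2)
  st <- new_state_with_one(roster, lat, B = 1e10, col = 2, row = 1)
  f <- metabolite_field(lat, c("s(e)", "p(e)"), unlimited = character())
  f$amounts["s(e)", 2, 1] <- 5
  set.seed(1)
  out <- metabolize_all(st, f, roster, a = 2)
  # hand LP: cap 2 over uptake+reaction+secretion (T = 3), flux 2/3
  flux <- 2 / 3
  expect_equal(unname(out$field$amounts["s(e)", 2, 1]), 5 - flux, tolerance = 1e-8)
  expect_equal(unname(out$field$amounts["p(e)", 2, 1]), flux, tolerance = 1e-8)
  expect_equal(out$growth, growth_from_atp(2 * flux, 1e10), tolerance = 1e-6)
  expect_equal(out$state$B[1], 1e10 + out$growth)

  # quiescent populations leave the pools untouched
  stq <- st; stq$quiescent <- TRUE
  outq <- metabolize_all(stq, f, roster, a = 2)
  expect_identical(outq$field$amounts, f$amounts)
  expect_equal(outq$growth, 0)

  # empty lattice is a no-op
  st0 <- new_community_state_public(lat)
  out0 <- metabolize_all(st0, f, roster)
  expect_identical(out0$field$amounts, f$amounts)
})

test_that("spreading halves populations into empty neighbours above threshold", {
  s <- small_setup(5, 5)
  roster <- s$roster
  st <- new_state_with_one(roster, s$lat, B = 1.2e10, col = 3, row = 3)
  set.seed(3)
  st2 <- spread(st, threshold = 1e10)
  expect_equal(length(st2$B), 2)
  expect_equal(st2$B, c(6e9, 6e9))
  expect_equal(sum(st2$B), 1.2e10)
  d <- max(abs(st2$col[2] - 3), abs(st2$row[2] - 3))
  expect_equal(d, 1) # Moore neighbour

  # below threshold: never splits
  stb <- new_state_with_one(roster, s$lat, B = 9e9, col = 3, row = 3)
  expect_equal(length(spread(stb)$B), 1)

  # no empty neighbour: unchanged
  stfull <- new_state_with_one(roster, s$lat, B = 1.2e10, col = 2, row = 2)
  for (cc in 1:3) for (rr in 1:3) {
    if (cc == 2 && rr == 2) next
    stfull$species <- c(stfull$species, 1L)
    stfull$B <- c(stfull$B, 5e7)
    stfull$col <- c(stfull$col, cc); stfull$row <- c(stfull$row, rr)
    stfull$quiescent <- c(stfull$quiescent, FALSE)
    stfull$occ[cc, rr] <- length(stfull$B)
  }
  expect_equal(length(spread(stfull)$B), length(stfull$B))
})

test_that("death removes populations at the configured probability", {
  s <- small_setup(40, 10)
  set.seed(5)
  st <- initialize_community(s$roster, s$lat, p = 0.9)
  n0 <- length(st$B)
  expect_equal(length(die(st, p = 0)$B), n0)
  set.seed(6)
  deaths <- n0 - length(die(st, p = 0.5)$B)
  expect_gt(deaths, n0 * 0.5 - 3 * sqrt(n0 * 0.25))
  expect_lt(deaths, n0 * 0.5 + 3 * sqrt(n0 * 0.25))
  # geometric lifetime: median ~ ln 2 / p
  set.seed(8)
  p <- 0.0075
  lives <- replicate(2000, {
    t <- 0L
    repeat { t <- t + 1L; if (runif(1) < p) break }
    t
  })
  expect_equal(median(lives), log(2) / p, tolerance = 0.1)
})

test_that("colonization fills only empty sites and can be disabled", {
  s <- small_setup(6, 4)
  st <- new_state_with_one(s$roster, s$lat, B = 5e7, col = 1, row = 1)
  set.seed(2)
  st2 <- colonize(st, s$roster, p = 1) # every empty site colonized
  expect_equal(length(st2$B), 6 * 4)
  expect_equal(attr(st2, "colonized"), 23L)
  expect_equal(anyDuplicated(cbind(st2$col, st2$row)), 0)
  st3 <- colonize(st2, s$roster, p = 1) # full lattice: nothing happens
  expect_equal(attr(st3, "colonized"), 0L)
  st4 <- colonize(st, s$roster, p = 0)
  expect_equal(length(st4$B), 1)
})

test_that("Kawasaki mixing conserves populations and site exclusivity", {
  s <- small_setup(12, 6)
  set.seed(9)
  st <- initialize_community(s$roster, s$lat, p = 0.4)
  n0 <- length(st$B)
  totB <- sum(st$B)
  for (k in 1:30) {
    st <- mix_populations(st)
    expect_equal(length(st$B), n0)
    expect_equal(sum(st$B), totB)
    expect_equal(anyDuplicated(cbind(st$col, st$row)), 0)
    expect_true(all(st$occ[cbind(st$col, st$row)] == seq_along(st$B)))
    expect_equal(sum(st$occ != 0), n0)
  }
})

test_that("well-mixed shuffling assigns random non-overlapping sites", {
  s <- small_setup(8, 8)
  set.seed(10)
  st <- initialize_community(s$roster, s$lat, p = 0.5)
  st2 <- well_mixed_shuffle(st)
  expect_equal(sort(st2$B), sort(st$B))
  expect_equal(anyDuplicated(cbind(st2$col, st2$row)), 0)
})

test_that("distal populations wash out", {
  s <- small_setup(7, 3)
  st <- new_state_with_one(s$roster, s$lat, B = 4e9, col = 7, row = 2)
  st2 <- remove_distal_populations(st)
  expect_equal(length(st2$B), 0)
  expect_equal(attr(st2, "removed_B"), 4e9)
})
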