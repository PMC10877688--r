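# Metabolite transport on the lattice: diffusion, advection, feeding,
# oxygen, well-mixed redistribution, and the derived transport constants.

one_substep_lattice <- function(width = 9, height = 9) {
  lat <- lattice_geometry("custom", width = width, height = height)
  lat$n_substeps <- 1
  lat
}

test_that("one diffusion substep spreads 14.25% to each nearest neighbour", {
  lat <- one_substep_lattice()
  f <- metabolite_field(lat, "x", unlimited = character(),
                        non_advected = character())
  f$amounts["x", 5, 5] <- 1
  f <- diffuse(f)
  expect_equal(unname(f$amounts["x", 5, 5]), 1 - 4 * 0.1425)
  expect_equal(unname(f$amounts["x", 4, 5]), 0.1425)
  expect_equal(unname(f$amounts["x", 5, 6]), 0.1425)
  expect_equal(unname(f$amounts["x", 4, 4]), 0) # no diagonal transport
})

test_that("diffusion leaves uniform fields unchanged and conserves mass", {
  lat <- lattice_geometry("custom", width = 12, height = 5)
  f <- metabolite_field(lat, c("x", "y"), unlimited = character(),
                        non_advected = character())
  f$amounts["x", , ] <- 0.37
  set.seed(7)
  f$amounts["y", , ] <- runif(12 * 5)
  tot0 <- field_totals(f)
  g <- f
  for (i in 1:25) g <- diffuse(g)
  expect_equal(max(abs(g$amounts["x", , ] - 0.37)), 0, tolerance = 1e-12)
  expect_equal(field_totals(g)$umol, tot0$umol, tolerance = 1e-13)
})

test_that("walls are no-flux: corner and edge sites keep their wall share", {
  lat <- one_substep_lattice(4, 4)
  f <- metabolite_field(lat, "x", unlimited = character(),
                        non_advected = character())
  f$amounts["x", 1, 1] <- 1
  f <- diffuse(f)
  expect_equal(unname(f$amounts["x", 1, 1]), 1 - 2 * 0.1425) # two neighbours only
  expect_equal(sum(f$amounts), 1)
})

test_that("advection shifts distally, spares oxygen, and removes distal mass", {
  lat <- lattice_geometry("custom", width = 6, height = 2)
  f <- metabolite_field(lat, c("x", "o2(e)"), unlimited = character())
  f$amounts["x", 3, 1] <- 1
  f$amounts["x", 6, 2] <- 0.5
  f$amounts["o2(e)", 4, 1] <- 0.2
  f <- advect(f, t = 1)
  expect_equal(unname(f$amounts["x", 4, 1]), 1)
  expect_equal(sum(f$amounts["x", 6, ]), 0) # old distal mass removed
  expect_equal(attr(f, "removed")[["x"]], 0.5)
  expect_equal(unname(f$amounts["o2(e)", 4, 1]), 0.2) # oxygen never advects
  f <- remove_distal_metabolites(f)
  expect_equal(sum(f$amounts["x", 6, ]), 0)

  empty <- metabolite_field(lat, "x", unlimited = character())
  empty <- advect(empty, 1)
  expect_equal(sum(empty$amounts), 0)
})

test_that("the coarse lattice advects every second step", {
  lat <- lattice_geometry("112x4")
  f <- metabolite_field(lat, "x", unlimited = character())
  f$amounts["x", 10, 1] <- 1
  f1 <- advect(f, t = 1)             # not due
  expect_equal(unname(f1$amounts["x", 10, 1]), 1)
  f2 <- advect(f, t = 2)
  expect_equal(unname(f2$amounts["x", 11, 1]), 1)
})

test_that("feeding splits the dose over the proximal sites on schedule", {
  lat <- lattice_geometry("225x8")
  f <- metabolite_field(lat, c("lcts(e)"), unlimited = character())
  fs <- feed_schedule(lactose = 211)
  f1 <- feed(f, fs, t = 1)
  expect_equal(unname(f1$amounts["lcts(e)", 3, 4]), 211 / 48)
  expect_equal(sum(f1$amounts["lcts(e)", 7:225, ]), 0)
  expect_identical(feed(f, fs, t = 2)$amounts, f$amounts) # off-period

  gos <- feed_schedule(lactose = 0, gos = 211)
  expect_equal(unname(gos$composition[c("gos_dp3(e)", "gos_dp4(e)", "gos_dp5(e)")]),
               c(135.04, 59.08, 16.88))
  expect_error(feed_schedule(gos = 10, gos_fractions = c(gos_dp3 = 0.5, gos_dp4 = 0.5, gos_dp5 = 0.2)),
               "sum to 1")
})

test_that("initial oxygen covers every site once", {
  lat <- lattice_geometry("225x8")
  f <- metabolite_field(lat, "o2(e)", unlimited = character())
  f <- init_oxygen(f, 0.1)
  expect_equal(sum(f$amounts["o2(e)", , ]), 180)
  f0 <- init_oxygen(metabolite_field(lat, "o2(e)", unlimited = character()), 0)
  expect_equal(sum(f0$amounts), 0)
  expect_error(init_oxygen(f, -0.1), "config error")
})

test_that("well-mixed redistribution equalizes and conserves", {
  lat <- lattice_geometry("225x8")
  f <- metabolite_field(lat, "x", unlimited = character())
  f$amounts["x", 2, 3] <- 48
  g <- well_mixed_redistribute(f)
  expect_equal(unname(g$amounts["x", 100, 5]), 48 / 1800)
  expect_equal(sum(g$amounts), 48)
  expect_equal(well_mixed_redistribute(g)$amounts, g$amounts)
})

test_that("the effective diffusion coefficient is identical across lattice variants", {
  Ds <- vapply(c("225x8", "112x4", "450x16"), function(v) {
    kernel_diffusion_coefficient(lattice_geometry(v))
  }, numeric(1))
  expect_equal(unname(Ds), rep(6.333333e-5, 3), tolerance = 1e-6)
  # deterministic tracer dispersion agrees with the analytic kernel value
  D_mc <- tracer_dispersion_coefficient(lattice_geometry("225x8"), n_steps = 40)
  expect_equal(D_mc, Ds[["225x8"]], tolerance = 0.02)
})
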