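# Run configuration, the canonical loop, determinism, and output bundles.

test_that("default configuration equals the standard parameter table", {
  cfg <- run_config()
  lat <- cfg$lattice
  expect_equal(lat$site_side_mm, 2)          # lattice side length, mm
  expect_equal(lat$width, 225)
  expect_equal(lat$height, 8)
  expect_equal(lat$timestep_s, 180)
  expect_equal(cfg$p_init * lat$width * lat$height, 540) # avg initial pops
  expect_equal(cfg$p_colonize, 5e-5)
  expect_equal(cfg$p_death, 0.0075)
  expect_equal(cfg$init_size, 5e7)
  expect_equal(cfg$spread_threshold, 1e10)
  expect_equal(cfg$max_size, 2e10)
  expect_equal(cfg$atp_per_cell, 1e-15)
  expect_equal(cfg$a, 2)                     # umol flux / step / 1e10 cells
  expect_equal(unname(cfg$feed$composition[["lcts(e)"]]), 211)
  expect_equal(cfg$feed$period, 60)
  expect_equal(cfg$oxygen, 0.1)
  expect_equal(lat$advect_cols * lat$site_side_mm / lat$advect_every, 2) # mm/step
  expect_equal(kernel_diffusion_coefficient(lat) * 1e5, 6.3, tolerance = 0.01)
  expect_equal(lat$site_volume_ml, 0.05)
  expect_equal(cfg$duration, 10080)
})

test_that("configurations round-trip losslessly through YAML", {
  cfg <- run_config(lattice = lattice_geometry("112x4"),
                    feed = feed_schedule(lactose = 100, gos = 50),
                    duration = 77, seed = 9, well_mixed = TRUE,
                    mixing_repeats = 5)
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$feed$composition, cfg$feed$composition)
  expect_equal(unclass(cfg2$lattice), unclass(cfg$lattice))
  cfg2$lattice <- NULL; cfg$lattice <- NULL
  cfg2$feed <- NULL; cfg$feed <- NULL
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("invalid configurations fail before any compute", {
  expect_error(run_config(p_death = 1.5), "probabilities")
  expect_error(run_config(duration = -1), "duration")
  expect_error(run_config(oxygen = -2), "oxygen")
  expect_error(run_config(init_size = 5e10), "max_size")
  expect_error(run_config(a = 0), "nonpositive")
})

test_that("zero-duration runs return only the initialized state", {
  cons <- make_crossfeeding_consortium()
  roster <- community_roster(cons$gems)
  cfg <- run_config(lattice = lattice_geometry("custom", width = 8, height = 3),
                    feed = cons$feeds$lactose_only, duration = 0, seed = 4)
  run <- run_simulation(cfg, roster)
  expect_equal(nrow(run$abundance), 1)
  expect_equal(nrow(run$ledger), 0)
  expect_true(all(run$populations$B == 5e7))
})

test_that("identical seed and configuration give identical outputs", {
  cons <- make_crossfeeding_consortium()
  roster <- community_roster(cons$gems)
  cfg <- run_config(lattice = lattice_geometry("custom", width = 10, height = 3),
                    feed = cons$feeds$lactose_2fl, duration = 60, seed = 12,
                    audit = FALSE)
  r1 <- run_simulation(cfg, roster)
  r2 <- run_simulation(cfg, roster)
  expect_identical(r1$populations, r2$populations)
  expect_identical(r1$abundance, r2$abundance)
  expect_identical(r1$ledger, r2$ledger)
  r3 <- run_simulation(run_config(lattice = cfg$lattice,
                                  feed = cons$feeds$lactose_2fl,
                                  duration = 60, seed = 13, audit = FALSE),
                       roster)
  expect_false(identical(r1$populations, r3$populations))
})

test_that("run objects tidy, glance, plot and export", {
  cons <- make_crossfeeding_consortium()
  roster <- community_roster(cons$gems)
  cfg <- run_config(lattice = lattice_geometry("custom", width = 10, height = 3),
                    feed = cons$feeds$lactose_2fl, duration = 40, seed = 2)
  run <- run_simulation(cfg, roster)

  td <- tidy(run)
  expect_true(all(c("t", "species", "cells", "rel_abundance") %in% names(td)))
  sums <- tapply(td$rel_abundance, td$t, sum)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-9 | sums == 0))

  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$duration, 40)

  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_abundance(run, relative = TRUE), "ggplot")

  out <- tempfile("bundle")
  write_run_outputs(run, out)
  expect_true(all(file.exists(file.path(out, c("abundance.csv",
                                               "populations.csv",
                                               "ledger.csv",
                                               "manifest.json")))))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2)
})

test_that("the per-step cell ledger balances growth, death, washout and colonization", {
  cons <- make_crossfeeding_consortium()
  roster <- community_roster(cons$gems)
  cfg <- run_config(lattice = lattice_geometry("custom", width = 12, height = 4),
                    feed = cons$feeds$lactose_2fl, duration = 150, seed = 21,
                    audit = FALSE, record_fluxes = FALSE)
  run <- run_simulation(cfg, roster)
  led <- run$ledger
  init_B <- sum(unlist(run$abundance[1, -1]))
  prev <- c(init_B, led$total_B[-nrow(led)])
  expected <- prev + led$growth - led$died_B - led$removed_B + led$colonized_B
  expect_equal(led$total_B, expected, tolerance = 1e-12)
  # abundance rows agree with the ledger totals
  expect_equal(rowSums(run$abundance[-1, -1]), led$total_B,
               tolerance = 1e-12, ignore_attr = TRUE)
})
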