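# SBML reading, normalization to irreversible reactions, exchange
# classification, and declarative patching.

toy_reversible_raw <- function() {
  list(id = "toy", objective = "DM_atp(c)", reactions = list(
    list(id = "EX_a(e)", stoich = c("a(e)" = -1), lb = -1000, ub = 1000),
    list(id = "CONV", stoich = c("a(e)" = -1, "b(e)" = 1), lb = -1000, ub = 1000),
    list(id = "EX_b(e)", stoich = c("b(e)" = -1), lb = -1000, ub = 1000),
    list(id = "MAKEATP", stoich = c("b(e)" = -1, "atp(c)" = 1)),
    list(id = "DM_atp(c)", stoich = c("atp(c)" = -1))
  ))
}

test_that("reversible reactions split into irreversible pairs with negated stoichiometry", {
  path <- tempfile(fileext = ".xml")
  write_gem_sbml(toy_reversible_raw(), path)
  gem <- load_gem(path)
  expect_true(all(c("CONV", "CONV_rev") %in% gem$reactions$id))
  expect_equal(gem$stoich[["CONV"]], c("a(e)" = -1, "b(e)" = 1))
  expect_equal(gem$stoich[["CONV_rev"]], -c("a(e)" = -1, "b(e)" = 1))
  expect_true(all(gem$reactions$lower_bound >= 0))
  # bounds of the pair cover the original range
  expect_equal(unname(gem$ub[["CONV"]]), 1000)
  expect_equal(unname(gem$ub[["CONV_rev"]]), 1000)
})

test_that("exchange reactions are classified and indexed by metabolite", {
  path <- tempfile(fileext = ".xml")
  write_gem_sbml(toy_reversible_raw(), path)
  gem <- load_gem(path)
  rx <- gem$reactions
  expect_true(all(rx$is_exchange[grepl("^(EX_|DM_)", rx$id)]))
  ex <- gem$exchange_index
  row <- ex[ex$metabolite == "a(e)", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$uptake, "EX_a(e)_rev")     # produces a(e): uptake
  expect_equal(row$secretion, "EX_a(e)")      # consumes a(e): secretion
  # the intracellular ATP demand is exchange-class but not coupled to the
  # environment
  expect_false(rx$env_coupled[rx$id == "DM_atp(c)"])
  expect_false("atp(c)" %in% ex$metabolite)
})

test_that("degenerate SBML inputs raise parse errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"><model id="empty"><listOfReactions/></model></sbml>', bad)
  expect_error(load_gem(bad), "zero reactions")
  notxml <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", notxml)
  expect_error(load_gem(notxml), "parse error")
})

test_that("SBML round trip preserves stoichiometry, bounds and objective", {
  path <- tempfile(fileext = ".xml")
  write_gem_sbml(toy_reversible_raw(), path)
  gem <- load_gem(path)
  expect_equal(gem$objective, "DM_atp(c)")
  expect_equal(sort(gem$mets), sort(c("a(e)", "b(e)", "atp(c)")))
  expect_equal(gem$stoich[["MAKEATP"]], c("b(e)" = -1, "atp(c)" = 1))
  expect_equal(unname(gem$ub[["MAKEATP"]]), 1000)
})

test_that("splitting reversible reactions preserves the feasible optimum", {
  # hand enumeration on the original reversible encoding: the only
  # productive route is a(e) uptake -> CONV forward -> MAKEATP, so a chain
  # flux x costs 3x of the summed-flux budget (objective excluded) and the
  # optimum is x = a/3 regardless of the encoding; the split encoding must
  # reproduce it
  path <- tempfile(fileext = ".xml")
  write_gem_sbml(toy_reversible_raw(), path)
  gem <- load_gem(path)
  a <- 3
  sol <- solve_fba(gem, c(), 1e10, a = a, unlimited = "a(e)")
  expect_equal(sol$atp_flux, a / 3, tolerance = 1e-9)
  expect_equal(unname(sol$uptake[["a(e)"]]), a / 3, tolerance = 1e-9)
})

test_that("patches apply in order, purely, and report dangling references", {
  path <- tempfile(fileext = ".xml")
  write_gem_sbml(toy_reversible_raw(), path)
  gem <- load_gem(path)

  expect_identical(apply_patch(gem, model_patch("toy"))$stoich, gem$stoich)

  p <- model_patch("toy", list(patch_block_uptake("a(e)")))
  patched <- apply_patch(gem, p)
  expect_equal(unname(patched$ub[["EX_a(e)_rev"]]), 0)
  expect_equal(unname(patched$ub[["EX_a(e)"]]), 1000) # secretion unchanged
  expect_equal(unname(gem$ub[["EX_a(e)_rev"]]), 1000) # original untouched
  # idempotent in outcome
  expect_equal(apply_patch(gem, p)$ub, patched$ub)

  expect_error(apply_patch(gem, model_patch("other")), "targets")
  expect_error(apply_patch(gem, model_patch("toy", list(
    patch_remove_reaction("NOPE")))), "NOPE")
  expect_error(apply_patch(gem, model_patch("toy", list(
    patch_add_reaction("CONV", c("a(e)" = -1))))), "already exists")
  expect_error(apply_patch(gem, model_patch("toy", list(
    patch_block_uptake("zz(e)")))), "zz\\(e\\)")
})

test_that("patch documents round-trip through YAML", {
  p <- model_patch("toy", list(
    patch_set_bound("CONV", 0, 5),
    patch_block_uptake("a(e)")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(target_species = "toy", actions = list(
    list(verb = "set_bound", id = "CONV", lower = 0, upper = 5),
    list(verb = "block_uptake", metabolite = "a(e)"))), path)
  q <- read_patch(path)
  expect_equal(q$target_species, "toy")
  expect_equal(length(q$actions), 2)
  expect_equal(q$actions[[1]]$upper, 5)
  expect_equal(q$actions[[2]]$metabolite, "a(e)")
})

test_that("prebiotic pathway patches wire 2'-FL and GOS digestion correctly", {
  cons <- make_crossfeeding_consortium()
  bif <- cons$gems$bifido

  # GOS: feeding only DP5 must allow growth (two extracellular cleavages,
  # ABC transport, hydrolysis, then lactose + galactose fermentation)
  sol <- solve_fba(bif, c("gos_dp5(e)" = 10), 1e10, a = 2)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$atp_flux, 0)
  expect_gt(unname(sol$uptake[["gos_dp5(e)"]]), 0)

  # 2'-FL: fucosidase conserves carbon (18 = 12 + 6) and all patch-added
  # reactions balance C exactly, H and O up to water of condensation
  bal <- element_balance(bif)
  patched_ids <- bif$reactions$id[bif$reactions$source == "patch" &
                                    !bif$reactions$is_exchange]
  sub <- bal[bal$id %in% patched_ids, ]
  expect_true(all(abs(sub$dC) < 1e-9))
  expect_true(all(sub$water_balanced))

  # the patch requires its prerequisite metabolites
  spec <- toy_gem_spec("plain", list(
    list(substrate = "s", products = c(), n_reactions = 1, atp = 1)))
  expect_error(add_prebiotic_pathways(make_toy_gem(spec), "2FL"),
               "prerequisite")
})
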