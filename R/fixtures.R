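# Synthetic toy GEMs with analytically known optima, and a three-species
# cross-feeding consortium emulating the lactose -> {lactate, acetate,
# 1,2-PD} -> butyrate food web. Fixtures are serialized as SBML and read
# back through the regular loader so the whole pipeline is exercised
# without any database download.

#' Specify a toy GEM
#'
#' A toy model is a set of linear pathways. Each pathway takes up one
#' extracellular substrate through an exchange + a chain of
#' `n_reactions` internal reactions, releases its products through their
#' exchanges, and yields `atp` per substrate molecule into the shared ATP
#' pool consumed by the `DM_atp(c)` objective.
#'
#' Under the enzymatic constraint `a` (summed flux excluding the
#' objective), the optimal ATP flux has the closed form
#' `a * max_k(atp_k / T_k)` with `T_k = 1 + n_reactions_k +
#' sum(products_k)` — see [toy_gem_optimum()].
#'
#' @param name Species id.
#' @param pathways List of pathways: each a list with `substrate`
#'   (compartment-free id), `products` (named numeric, molecules produced
#'   per substrate; may be empty), `n_reactions` (internal chain length,
#'   >= 1) and `atp` (yield per substrate).
#' @return An object of class `toy_gem_spec`.
#' @export
toy_gem_spec <- function(name, pathways) {
  stopifnot(length(pathways) >= 1)
  for (p in pathways) {
    stopifnot(!is.null(p$substrate), p$n_reactions >= 1, p$atp >= 0)
  }
  structure(list(name = name, pathways = pathways), class = "toy_gem_spec")
}

#' Closed-form optimum of a toy GEM
#'
#' @param spec A [toy_gem_spec()].
#' @param a Enzymatic constraint.
#' @return Optimal ATP flux (umol per timestep per population unit) with
#'   every substrate unlimited.
#' @export
toy_gem_optimum <- function(spec, a) {
  ratios <- vapply(spec$pathways, function(p) {
    T_k <- 1 + p$n_reactions + sum(p$products)
    p$atp / T_k
  }, numeric(1))
  a * max(ratios)
}

toy_gem_raw <- function(spec) {
  ec <- function(x) paste0(x, "(e)")
  reactions <- list()
  add <- function(id, stoich, lb = 0, ub = 1000) {
    reactions[[length(reactions) + 1]] <<-
      list(id = id, stoich = stoich, lb = lb, ub = ub)
  }
  ex_added <- character()
  add_ex <- function(met) {
    rid <- paste0("EX_", met)
    if (!rid %in% ex_added) {
      add(rid, setNames(-1, met), lb = -1000, ub = 1000)
      ex_added <<- c(ex_added, rid)
    }
  }
  for (k in seq_along(spec$pathways)) {
    p <- spec$pathways[[k]]
    sub_e <- ec(p$substrate)
    add_ex(sub_e)
    chain_in <- sub_e
    if (p$n_reactions > 1) {
      for (j in seq_len(p$n_reactions - 1)) {
        mid <- paste0("pw", k, "_i", j, "(c)")
        add(paste0("PW", k, "_R", j), setNames(c(-1, 1), c(chain_in, mid)))
        chain_in <- mid
      }
    }
    stoich <- setNames(-1, chain_in)
    if (length(p$products)) {
      prod_e <- ec(names(p$products))
      stoich[prod_e] <- unname(p$products)
      for (m in prod_e) add_ex(m)
    }
    if (p$atp > 0) stoich["atp(c)"] <- p$atp
    add(paste0("PW", k, "_R", p$n_reactions), stoich)
  }
  add("DM_atp(c)", c("atp(c)" = -1))
  list(id = spec$name, reactions = reactions, objective = "DM_atp(c)")
}

#' Build a toy GEM
#'
#' Serializes the spec to SBML (AGORA dialect) and reads it back through
#' [load_gem()], so the fixture exercises the real reader.
#'
#' @param spec A [toy_gem_spec()].
#' @param path Optional SBML output path (a temp file by default).
#' @return A [gem_model()] with the spec attached as attribute `"spec"`.
#' @export
make_toy_gem <- function(spec, path = tempfile(fileext = ".xml")) {
  write_gem_sbml(toy_gem_raw(spec), path)
  gem <- load_gem(path, species_id = spec$name, objective = "DM_atp(c)")
  attr(gem, "spec") <- spec
  gem
}

consortium_raw <- function() {
  list(
    bifido = list(
      id = "bifido",
      objective = "DM_atp(c)",
      reactions = list(
        list(id = "EX_lcts(e)", stoich = c("lcts(e)" = -1), lb = -1000, ub = 1000),
        list(id = "LCTSt", stoich = c("lcts(e)" = -1, "lcts(c)" = 1)),
        # bifid-shunt-like: lactose -> 3 acetate + 2 lactate
        list(id = "LCTSferm", stoich = c("lcts(c)" = -1, "ac(e)" = 3,
                                         "lac(e)" = 2, "atp(c)" = 16)),
        # fucose fermentation: the 1,2-PD source once 2'-FL is digested
        list(id = "FUCferm", stoich = c("fuc(c)" = -1, "12ppd(e)" = 1,
                                        "ac(e)" = 1, "co2(e)" = 1,
                                        "h2(e)" = 1, "atp(c)" = 20)),
        # galactose fermentation, used by the GOS route
        list(id = "GALferm", stoich = c("gal(c)" = -1, "lac(e)" = 2,
                                        "atp(c)" = 2)),
        list(id = "EX_ac(e)", stoich = c("ac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_lac(e)", stoich = c("lac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_12ppd(e)", stoich = c("12ppd(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_co2(e)", stoich = c("co2(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_h2(e)", stoich = c("h2(e)" = -1), lb = -1000, ub = 1000),
        list(id = "DM_atp(c)", stoich = c("atp(c)" = -1))
      )
    ),
    producer = list(
      id = "producer",
      objective = "DM_atp(c)",
      reactions = list(
        list(id = "EX_lac(e)", stoich = c("lac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "LACt", stoich = c("lac(e)" = -1, "lac(c)" = 1)),
        # 2 lactate -> butyrate + 2 CO2 + 2 H2 (poorest yield-per-flux)
        list(id = "LACferm", stoich = c("lac(c)" = -2, "but(e)" = 1,
                                        "co2(e)" = 2, "h2(e)" = 2,
                                        "atp(c)" = 3)),
        list(id = "EX_12ppd(e)", stoich = c("12ppd(e)" = -1), lb = -1000, ub = 1000),
        list(id = "PPDt", stoich = c("12ppd(e)" = -1, "12ppd(c)" = 1)),
        list(id = "EX_ac(e)", stoich = c("ac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "ACt", stoich = c("ac(e)" = -1, "ac(c)" = 1)),
        # 1,2-PD + acetate -> butyrate + CO2 + 2 H2: the producer's
        # distinctive high-yield-per-flux substrate
        list(id = "PPDferm", stoich = c("12ppd(c)" = -1, "ac(c)" = -1,
                                        "but(e)" = 1, "co2(e)" = 1,
                                        "h2(e)" = 2, "atp(c)" = 24)),
        list(id = "EX_but(e)", stoich = c("but(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_co2(e)", stoich = c("co2(e)" = -1), lb = -1000, ub = 1000),
        list(id = "EX_h2(e)", stoich = c("h2(e)" = -1), lb = -1000, ub = 1000),
        list(id = "DM_atp(c)", stoich = c("atp(c)" = -1))
      )
    ),
    competitor = list(
      id = "competitor",
      objective = "DM_atp(c)",
      reactions = list(
        list(id = "EX_lcts(e)", stoich = c("lcts(e)" = -1), lb = -1000, ub = 1000),
        list(id = "LCTSt", stoich = c("lcts(e)" = -1, "lcts(c)" = 1)),
        list(id = "LCTSferm", stoich = c("lcts(c)" = -1, "lac(e)" = 2,
                                         "ac(e)" = 3, "atp(c)" = 10)),
        list(id = "EX_lac(e)", stoich = c("lac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "LACt", stoich = c("lac(e)" = -1, "lac(c)" = 1)),
        # better lactate yield-per-flux than the producer: the basis of
        # competitive exclusion without 1,2-PD
        list(id = "LACferm", stoich = c("lac(c)" = -2, "ac(e)" = 3,
                                        "atp(c)" = 7)),
        list(id = "EX_ac(e)", stoich = c("ac(e)" = -1), lb = -1000, ub = 1000),
        list(id = "DM_atp(c)", stoich = c("atp(c)" = -1))
      )
    )
  )
}

#' Build the synthetic cross-feeding consortium
#'
#' Three toy species emulating the mechanism by which 2'-fucosyllactose
#' supports butyrate producers:
#'
#' * `bifido` ferments lactose to lactate + acetate and, via the 2'-FL
#'   pathway added with [add_prebiotic_pathways()], releases
#'   1,2-propanediol (plus a GOS digestion route);
#' * `producer` (the butyrate producer) ferments lactate to butyrate, and
#'   1,2-PD + acetate to butyrate at its highest yield-per-flux;
#' * `competitor` consumes lactose and lactate, with a better lactate
#'   yield-per-flux than the producer (so it excludes the producer unless
#'   1,2-PD is available), and cannot use 1,2-PD.
#'
#' All reactions conserve carbon exactly and hydrogen/oxygen up to the
#' water-of-condensation convention. Yield-per-flux ratios (ATP per summed
#' flux): producer 1,2-PD(+acetate) 24/9 > bifido 2'-FL 35/14 > bifido
#' lactose 16/8 > competitor lactose 10/8 > competitor lactate 7/8 >
#' producer lactate 3/10. The ordering encodes the mechanism: the
#' prebiotic consumer takes 2'-FL even when lactose is present (so 1,2-PD
#' flows as soon as 2'-FL is fed), the competitor beats the producer on
#' lactate, and only 1,2-PD gives the producer a winning substrate. These
#' are design constants of the generator, documented here, not tuned per
#' test.
#'
#' @param lattice A [lattice_geometry()] the feeds are scaled to: feed
#'   doses are the standard dose (211 umol per nutrient per 60 timesteps)
#'   scaled by the lattice's share of the default 90 mL colon volume. The
#'   default desk-scale lattice is a 20 x 4 section of the default
#'   parameterization (2 x 2 mm sites, 0.05 mL per site), i.e. 4 cm of
#'   colon with the standard transport constants.
#' @param dir Directory for the SBML files (a temp dir by default).
#' @return List with `gems` (named list of [gem_model()]s: bifido with the
#'   2'-FL and GOS pathways applied, producer, competitor), `feeds`
#'   (`lactose_only` and `lactose_2fl` [feed_schedule()]s), `producers`
#'   (names of the butyrate-producing group), `lattice`, and `dose`.
#' @export
make_crossfeeding_consortium <- function(lattice = lattice_geometry("custom",
                                                                    width = 20,
                                                                    height = 4),
                                         dir = tempfile("consortium")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raws <- consortium_raw()
  gems <- lapply(raws, function(raw) {
    path <- file.path(dir, paste0(raw$id, ".xml"))
    write_gem_sbml(raw, path)
    load_gem(path, species_id = raw$id, objective = raw$objective)
  })
  gems$bifido <- add_prebiotic_pathways(gems$bifido, "2FL")
  gems$bifido <- add_prebiotic_pathways(gems$bifido, "GOS")
  scale <- lattice$width * lattice$height * lattice$site_volume_ml / 90
  dose <- 211 * scale
  list(
    gems = gems,
    feeds = list(
      lactose_only = feed_schedule(lactose = dose),
      lactose_2fl = feed_schedule(lactose = dose, fl2 = dose)
    ),
    producers = "producer",
    lattice = lattice,
    dose = dose
  )
}
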