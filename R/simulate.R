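# Run configuration and the canonical simulation loop. The phase order
# within a timestep is fixed (and documented in the methods vignette):
# feed -> metabolism/growth (random population order) -> spreading ->
# quiescence flags -> death -> colonization -> mixing -> metabolite
# diffusion -> advection -> distal removal (metabolites, then populations)
# -> recording.

#' Simulation run configuration
#'
#' Defaults are the model's standard parameter set: 225 x 8 lattice of
#' 2 mm sites, 180 s timestep, on average 540 initial populations (p =
#' 0.3) of 5e7 cells, colonization probability 5e-5 per empty site per
#' step, death probability 0.0075 per population per step, spreading at
#' 1e10 cells, maximum size 2e10 cells, 1e-15 mol ATP per new cell,
#' enzymatic constraint 2 umol flux per timestep per 1e10 bacteria,
#' feeding 211 umol lactose per 60 timesteps, initial oxygen 0.1 umol per
#' site, and 10080 timesteps (21 days).
#'
#' @param lattice A [lattice_geometry()] or variant name.
#' @param feed A [feed_schedule()].
#' @param duration Number of timesteps.
#' @param seed Integer seed for the run's random number generator.
#' @param a Enzymatic constraint, umol flux per timestep per unit.
#' @param p_init Initial occupancy probability per site.
#' @param init_size Initial (and colonizing) population size, cells.
#' @param spread_threshold Size needed to create a new population, cells.
#' @param max_size Maximum population size, cells.
#' @param p_death Death probability per population per timestep.
#' @param p_colonize Colonization probability per empty site per timestep.
#' @param atp_per_cell ATP to grow one cell, mol.
#' @param oxygen Initial oxygen, umol per site.
#' @param mixing_repeats Kawasaki passes per timestep (5 = fast variant).
#' @param mixing_fraction Fraction of sites swapping per pass (0.2 = slow
#'   variant).
#' @param well_mixed Replace spatial transport/mixing by global
#'   redistribution.
#' @param colonization,quiescence Feature switches (sensitivity variants).
#' @param audit Record the Gibbs free-energy audit.
#' @param energy_table_path Optional CSV for the audit's energy table.
#' @param record_fluxes Record per-species exchange fluxes per timestep.
#' @param unlimited Metabolites with unlimited supply.
#' @param non_advected Metabolites exempt from advection.
#' @param constraint_scope See [solve_fba()].
#' @return An object of class `gut_run_config`.
#' @export
run_config <- function(lattice = lattice_geometry("225x8"),
                       feed = feed_schedule(),
                       duration = 10080,
                       seed = 1L,
                       a = 2,
                       p_init = 0.3,
                       init_size = 5e7,
                       spread_threshold = 1e10,
                       max_size = 2e10,
                       p_death = 0.0075,
                       p_colonize = 5e-5,
                       atp_per_cell = 1e-15,
                       oxygen = 0.1,
                       mixing_repeats = 1,
                       mixing_fraction = 1,
                       well_mixed = FALSE,
                       colonization = TRUE,
                       quiescence = TRUE,
                       audit = TRUE,
                       energy_table_path = NULL,
                       record_fluxes = TRUE,
                       unlimited = "h2o(e)",
                       non_advected = "o2(e)",
                       constraint_scope = "all_but_objective") {
  if (is.character(lattice)) lattice <- lattice_geometry(lattice)
  cfg <- list(lattice = lattice, feed = feed, duration = duration,
              seed = as.integer(seed), a = a, p_init = p_init,
              init_size = init_size, spread_threshold = spread_threshold,
              max_size = max_size, p_death = p_death,
              p_colonize = p_colonize, atp_per_cell = atp_per_cell,
              oxygen = oxygen, mixing_repeats = mixing_repeats,
              mixing_fraction = mixing_fraction, well_mixed = well_mixed,
              colonization = colonization, quiescence = quiescence,
              audit = audit, energy_table_path = energy_table_path,
              record_fluxes = record_fluxes, unlimited = unlimited,
              non_advected = non_advected,
              constraint_scope = constraint_scope)
  validate_run_config(structure(cfg, class = "gut_run_config"))
}

validate_run_config <- function(cfg) {
  probs <- c(p_init = cfg$p_init, p_death = cfg$p_death,
             p_colonize = cfg$p_colonize)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("config error: probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (cfg$duration < 0) stop("config error: duration must be >= 0")
  for (f in c("a", "init_size", "spread_threshold", "max_size",
              "atp_per_cell")) {
    if (cfg[[f]] <= 0) stop("config error: nonpositive parameter '", f, "'")
  }
  if (cfg$oxygen < 0) stop("config error: negative initial oxygen")
  if (cfg$init_size > cfg$max_size) {
    stop("config error: init_size exceeds max_size")
  }
  cfg
}

#' @export
print.gut_run_config <- function(x, ...) {
  cat("<gut_run_config> ", x$lattice$width, "x", x$lattice$height,
      " lattice, ", x$duration, " steps, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write/read a run configuration as YAML
#'
#' The YAML round-trip is lossless for every configuration field.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `path` / the re-read `gut_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$lattice <- unclass(lst$lattice)
  lst$feed <- list(period = cfg$feed$period, columns = cfg$feed$columns,
                   composition = as.list(cfg$feed$composition))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lat <- structure(lst$lattice, class = "gut_lattice")
  comp <- unlist(lst$feed$composition)
  fs <- structure(list(period = lst$feed$period, columns = lst$feed$columns,
                       composition = comp), class = "feed_schedule")
  lst$lattice <- lat
  lst$feed <- fs
  lst$seed <- as.integer(lst$seed)
  validate_run_config(structure(lst, class = "gut_run_config"))
}

#' Run a community simulation
#'
#' Executes the canonical timestep loop for `config$duration` steps.
#' Identical `config` + `roster` + seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param roster A [community_roster()].
#' @return An object of class `gutsim_run` with elements `abundance`
#'   (tibble, one row per timestep, one column per species, cells),
#'   `populations` (final population table), `flux_records` (tidy tibble
#'   of per-step per-species exchange fluxes, umol), `ledger` (per-step
#'   cell bookkeeping), `audit` (summary list or `NULL`), `field_totals`
#'   (final metabolite totals) and `config`.
#' @export
run_simulation <- function(config, roster) {
  stopifnot(inherits(config, "gut_run_config"),
            inherits(roster, "community_roster"))
  set.seed(config$seed)
  lattice <- config$lattice
  mets <- unique(c(roster_metabolites(roster), names(config$feed$composition),
                   "o2(e)", config$unlimited))
  field <- metabolite_field(lattice, mets, unlimited = config$unlimited,
                            non_advected = config$non_advected)
  field <- init_oxygen(field, config$oxygen)
  state <- initialize_community(roster, lattice, config$p_init,
                                config$init_size)
  audit <- if (config$audit) {
    energy_audit(energy_table(config$energy_table_path))
  } else NULL

  nsp <- length(roster$species)
  ab <- matrix(0, config$duration + 1, nsp,
               dimnames = list(NULL, roster$species))
  ab[1, ] <- species_totals(state, nsp)
  ledger <- matrix(0, config$duration, 6,
                   dimnames = list(NULL, c("t", "growth", "died_B",
                                           "colonized_B", "removed_B",
                                           "total_B")))
  flux_rows <- vector("list", config$duration)

  t <- 0L
  while (t < config$duration) {
    t <- t + 1L
    state$t <- t
    field <- feed(field, config$feed, t)
    mz <- metabolize_all(state, field, roster, a = config$a,
                         max_size = config$max_size,
                         atp_per_cell = config$atp_per_cell,
                         audit = audit, record = config$record_fluxes)
    state <- mz$state; field <- mz$field; audit <- mz$audit
    state <- spread(state, config$spread_threshold)
    state <- update_quiescence(state, config$max_size, config$quiescence)
    state <- die(state, config$p_death)
    died_B <- attr(state, "died_B")
    state <- colonize(state, roster,
                      p = if (config$colonization) config$p_colonize else 0,
                      size = config$init_size)
    colonized_B <- attr(state, "colonized") * config$init_size
    if (config$well_mixed) {
      state <- well_mixed_shuffle(state)
      field <- well_mixed_redistribute(field)
    } else {
      state <- mix_populations(state, config$mixing_repeats,
                               config$mixing_fraction)
      field <- diffuse(field)
    }
    field <- advect(field, t)
    field <- remove_distal_metabolites(field)
    state <- remove_distal_populations(state)
    removed_B <- attr(state, "removed_B")

    ab[t + 1, ] <- species_totals(state, nsp)
    ledger[t, ] <- c(t, mz$growth, died_B, colonized_B, removed_B,
                     sum(state$B))
    if (config$record_fluxes) {
      flux_rows[[t]] <- melt_flux(mz$uptake, mz$secretion, t)
    }
  }

  structure(
    list(
      config = config,
      abundance = tibble::as_tibble(cbind(t = 0:config$duration,
                                          as.data.frame(ab))),
      populations = population_table(state, roster),
      flux_records = if (config$record_fluxes) {
        dplyr::bind_rows(flux_rows)
      } else NULL,
      ledger = tibble::as_tibble(as.data.frame(ledger)),
      audit = if (!is.null(audit) && audit$n_total > 0) {
        audit_summary(audit)
      } else NULL,
      field_totals = field_totals(field)
    ),
    class = "gutsim_run"
  )
}

species_totals <- function(state, nsp) {
  tot <- numeric(nsp)
  if (length(state$B)) {
    agg <- rowsum(state$B, state$species)
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  tot
}

melt_flux <- function(up, sec, t) {
  out <- list()
  nz <- which(up > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    out$up <- tibble::tibble(t = t, species = rownames(up)[nz[, 1]],
                             metabolite = colnames(up)[nz[, 2]],
                             direction = "uptake", umol = up[nz])
  }
  nz <- which(sec > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    out$sec <- tibble::tibble(t = t, species = rownames(sec)[nz[, 1]],
                              metabolite = colnames(sec)[nz[, 2]],
                              direction = "secretion", umol = sec[nz])
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}

#' @export
print.gutsim_run <- function(x, ...) {
  cat("<gutsim_run> ", x$config$duration, " steps on ",
      x$config$lattice$width, "x", x$config$lattice$height, " lattice\n",
      "  final populations: ", nrow(x$populations),
      "; total cells: ", format(sum(x$populations$B), digits = 4), "\n",
      sep = "")
  if (!is.null(x$audit)) {
    cat("  audit: ", format(x$audit$fraction_plausible, digits = 6),
        "% of ", x$audit$n_solutions, " solutions plausible\n", sep = "")
  }
  invisible(x)
}

#' Tidy a simulation run into a long abundance table
#'
#' @param x A `gutsim_run`.
#' @param ... Unused.
#' @return Tibble (t, species, cells, rel_abundance).
#' @export
tidy.gutsim_run <- function(x, ...) relative_abundances(x$abundance)

#' One-row summary of a simulation run
#'
#' @param x A `gutsim_run`.
#' @param ... Unused.
#' @return One-row tibble: duration, species count, final populations,
#'   final total cells, and (when audited) the percentage of
#'   thermodynamically plausible FBA solutions.
#' @export
glance.gutsim_run <- function(x, ...) {
  tibble::tibble(
    duration = x$config$duration,
    n_species = ncol(x$abundance) - 1L,
    n_populations = nrow(x$populations),
    total_cells = sum(x$populations$B),
    fraction_plausible = if (!is.null(x$audit)) {
      x$audit$fraction_plausible
    } else NA_real_
  )
}

#' Write a run's output bundle
#'
#' Writes tidy CSVs (abundances, final populations, flux records, ledger),
#' the audit report as JSON, and a manifest (configuration + seed +
#' package version) for provenance.
#'
#' @param run A `gutsim_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$abundance, file.path(dir, "abundance.csv"), row.names = FALSE)
  write.csv(run$populations, file.path(dir, "populations.csv"),
            row.names = FALSE)
  if (!is.null(run$flux_records)) {
    write.csv(run$flux_records, file.path(dir, "fluxes.csv"),
              row.names = FALSE)
  }
  write.csv(run$ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  if (!is.null(run$audit)) {
    jsonlite::write_json(run$audit, file.path(dir, "audit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(package = "gutsim",
                   version = as.character(utils::packageVersion("gutsim")),
                   seed = run$config$seed,
                   duration = run$config$duration,
                   lattice = paste0(run$config$lattice$width, "x",
                                    run$config$lattice$height))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Growth assays for every roster species
#'
#' @param roster A [community_roster()].
#' @param substrates Named concentrations (umol/mL, `Inf` = unlimited).
#' @param ... Passed to [growth_assay()].
#' @return Tibble with one row per species, sorted by growth.
#' @export
assay_roster <- function(roster, substrates, ...) {
  out <- dplyr::bind_rows(lapply(roster$gems, growth_assay,
                                 substrates = substrates, ...))
  dplyr::arrange(out, dplyr::desc(.data$growth_per_cell))
}
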