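# Observables: abundance records, the carbon-weighted cross-feeding flux
# network, butyrate-producer persistence counts, and single-timestep growth
# assays.

#' Load a metabolite element-composition table
#'
#' @param path CSV path with columns `metabolite` (compartment-free id),
#'   `C`, `H`, `O`; `NULL` for the bundled table.
#' @return A tibble.
#' @export
composition_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "composition.csv", package = "gutsim")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

carbon_content <- function(metabolites, composition = composition_table()) {
  base <- sub("\\([ec]\\)$", "", metabolites)
  hit <- match(base, composition$metabolite)
  if (anyNA(hit)) {
    stop("composition table lacks metabolite(s): ",
         paste(unique(metabolites[is.na(hit)]), collapse = ", "))
  }
  setNames(composition$C[hit], metabolites)
}

#' Carbon-weighted cross-feeding flux network
#'
#' Aggregates per-species exchange fluxes over the trailing window,
#' multiplies by the carbon content of each molecule, and keeps edges of at
#' least `threshold` umol atomic carbon. Secretions are edges species ->
#' metabolite pool; uptakes are pool -> species. Pools are lattice-global.
#'
#' @param flux_records Tidy tibble of exchange records with columns `t`,
#'   `species`, `metabolite`, `direction` (`"uptake"`/`"secretion"`) and
#'   `umol`, as produced by [run_simulation()].
#' @param window Number of trailing timesteps to aggregate (the last 3 h
#'   at defaults).
#' @param threshold Minimum edge weight, umol atomic carbon.
#' @param composition Element-composition table.
#' @param combine_lactate Merge L- and D-lactate pools (`lac_L`/`lac_D`)
#'   into a single `lac` pool.
#' @return A tibble of class `flux_network` with columns `from`, `to`,
#'   `metabolite`, `umol`, `umol_carbon`.
#' @export
flux_network <- function(flux_records, window = 60, threshold = 100,
                         composition = composition_table(),
                         combine_lactate = FALSE) {
  stopifnot(nrow(flux_records) == 0 || all(
    c("t", "species", "metabolite", "direction", "umol") %in% names(flux_records)))
  if (nrow(flux_records) == 0) {
    out <- tibble::tibble(from = character(), to = character(),
                          metabolite = character(), umol = numeric(),
                          umol_carbon = numeric())
    return(structure(out, class = c("flux_network", class(out))))
  }
  t_end <- max(flux_records$t)
  rec <- dplyr::filter(flux_records, .data$t > t_end - window)
  if (combine_lactate) {
    rec$metabolite <- sub("^lac_[LD]", "lac", rec$metabolite)
  }
  agg <- rec |>
    dplyr::group_by(.data$species, .data$metabolite, .data$direction) |>
    dplyr::summarise(umol = sum(.data$umol), .groups = "drop")
  agg$umol_carbon <- unname(agg$umol * carbon_content(agg$metabolite, composition))
  agg <- dplyr::filter(agg, .data$umol_carbon >= threshold)
  out <- tibble::tibble(
    from = ifelse(agg$direction == "secretion", agg$species, agg$metabolite),
    to = ifelse(agg$direction == "secretion", agg$metabolite, agg$species),
    metabolite = agg$metabolite, umol = agg$umol,
    umol_carbon = agg$umol_carbon
  )
  structure(out[order(out$from, out$to), ],
            class = c("flux_network", class(out)))
}

#' Convert a flux network to an igraph graph
#'
#' @param net A [flux_network()].
#' @return An igraph directed graph; vertices carry a `type` attribute
#'   (`"species"` or `"pool"`).
#' @export
flux_network_graph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$from, to = net$to, weight = net$umol_carbon),
    directed = TRUE
  )
  pools <- unique(net$metabolite)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% pools, "pool", "species")
  g
}

#' Write a flux network as edge-list CSV or GraphML
#'
#' @param net A [flux_network()].
#' @param path Output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_flux_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(net), path, row.names = FALSE)
  } else {
    igraph::write_graph(flux_network_graph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Count runs in which butyrate producers persist
#'
#' Sums the final abundance of the butyrate-producing group per run and
#' counts runs whose combined abundance exceeds the cutoff.
#'
#' @param final_abundances Tibble with columns `run`, `species`, `cells`
#'   and optionally `condition`.
#' @param producers Character vector naming the butyrate-producing species.
#' @param cutoff Combined-abundance cutoff, cells.
#' @return Tibble per condition (or overall) with `n_runs`, `n_above`.
#' @export
butyrate_persistence <- function(final_abundances, producers, cutoff = 1e10) {
  known <- unique(final_abundances$species)
  unknown <- setdiff(producers, known)
  if (length(unknown)) {
    stop("config error: unknown species in producer group: ",
         paste(unknown, collapse = ", "))
  }
  fa <- final_abundances
  if (!"condition" %in% names(fa)) fa$condition <- "all"
  fa |>
    dplyr::group_by(.data$condition, .data$run) |>
    dplyr::summarise(
      combined = sum(.data$cells[.data$species %in% producers]),
      .groups = "drop_last") |>
    dplyr::summarise(n_runs = dplyr::n(),
                     n_above = sum(.data$combined > cutoff),
                     .groups = "drop")
}

#' Single-timestep growth assay
#'
#' Gives a population of `B` cells access to one lattice site's volume with
#' the stated substrate concentrations (plus unlimited water), solves one
#' FBA problem and reports the growth over a single timestep. Used to rank
#' species by growth on lactose, lactate, or 1,2-PD + acetate.
#'
#' @param gem A [gem_model()].
#' @param substrates Named numeric vector of concentrations in umol/mL;
#'   `Inf` marks an unlimited substrate.
#' @param B Population size, cells.
#' @param site_volume Site volume, mL.
#' @param a Enzymatic constraint.
#' @param atp_per_cell ATP to grow one cell, mol.
#' @return A one-row tibble: `species`, `atp_flux`, `delta_B`,
#'   `growth_per_cell` (= delta_B / B per timestep), `status`.
#' @export
growth_assay <- function(gem, substrates = c(), B = 5e9, site_volume = 0.05,
                         a = 2, atp_per_cell = 1e-15) {
  unlimited <- union("h2o(e)", names(substrates)[is.infinite(substrates)])
  finite <- substrates[is.finite(substrates)]
  env <- setNames(finite * site_volume, names(finite))
  sol <- solve_fba(gem, env, B, a = a, unlimited = unlimited)
  dB <- growth_from_atp(sol$atp_flux, B, atp_per_cell)
  tibble::tibble(species = gem$species_id, atp_flux = sol$atp_flux,
                 delta_B = dB, growth_per_cell = dB / B, status = sol$status)
}

#' Relative abundances from a wide abundance matrix
#'
#' @param abundance Tibble with a `t` column and one column per species
#'   (cells), as stored in a `gutsim_run`.
#' @return Long tibble (t, species, cells, rel_abundance); relative
#'   abundances sum to 1 wherever total biomass is positive.
#' @export
relative_abundances <- function(abundance) {
  long <- tidyr::pivot_longer(abundance, -"t", names_to = "species",
                              values_to = "cells")
  long |>
    dplyr::group_by(.data$t) |>
    dplyr::mutate(rel_abundance = if (sum(.data$cells) > 0)
      .data$cells / sum(.data$cells) else rep(0, dplyr::n())) |>
    dplyr::ungroup()
}
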