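# Gibbs free-energy audit of FBA solutions. The energy loss of a solution
# is l = sum_i (F_in(i) - F_out(i)) * E(i): free energy taken up minus free
# energy released. l >= 0 means free energy was dissipated (plausible);
# l < 0 flags a thermodynamically implausible solution. The audit is purely
# observational: it never alters the simulation trajectory.

#' Load a metabolite Gibbs free-energy table
#'
#' Reads a two-column CSV (`metabolite`, `kJ_per_mol`; pH 7, ionic strength
#' 0.1 M convention) and adds composite entries for the prebiotics:
#' 2'-FL = lactose + fucose - water (water of condensation) and
#' GOS DPn = lactose + (n-2) * (galactose - water).
#'
#' The bundled default table carries synthetic values for the fixture
#' metabolites (coherent, dissipative, but not literature estimates);
#' supply your own table for quantitative work.
#'
#' @param path CSV path; `NULL` for the bundled synthetic table.
#' @param composites Add the derived prebiotic entries.
#' @return Named numeric vector, kJ/mol.
#' @export
energy_table <- function(path = NULL, composites = TRUE) {
  path <- path %||% system.file("extdata", "energy_synthetic.csv",
                                package = "gutsim")
  tb <- read.csv(path, stringsAsFactors = FALSE)
  E <- setNames(tb$kJ_per_mol, tb$metabolite)
  if (composites) E <- derive_composite_energies(E)
  E
}

#' @rdname energy_table
#' @param E Named numeric vector of energies, kJ/mol, keyed by metabolite
#'   id (extracellular ids, e.g. `"lcts(e)"`).
#' @export
derive_composite_energies <- function(E) {
  need <- c("lcts(e)", "fuc(e)", "gal(e)", "h2o(e)")
  if (!all(need %in% names(E))) return(E)
  lcts <- E[["lcts(e)"]]; h2o <- E[["h2o(e)"]]
  if (!"2fl(e)" %in% names(E)) {
    E[["2fl(e)"]] <- lcts + E[["fuc(e)"]] - h2o
  }
  for (n in 3:5) {
    id <- paste0("gos_dp", n, "(e)")
    if (!id %in% names(E)) {
      E[[id]] <- lcts + (n - 2) * (E[["gal(e)"]] - h2o)
    }
  }
  E
}

#' Energy balance of one FBA solution
#'
#' @param solution An `fba_solution` from [solve_fba()].
#' @param E Energy table from [energy_table()].
#' @return Energy loss `l` in joules per timestep per population unit
#'   (umol exchange fluxes times kJ/mol); `l >= 0` is thermodynamically
#'   plausible.
#' @export
energy_balance <- function(solution, E) {
  mets <- union(names(solution$uptake), names(solution$secretion))
  missing <- setdiff(mets, names(E))
  if (length(missing)) {
    stop("audit error: no Gibbs energy for metabolite(s): ",
         paste(missing, collapse = ", "))
  }
  fin <- setNames(rep(0, length(mets)), mets)
  fout <- fin
  fin[names(solution$uptake)] <- solution$uptake
  fout[names(solution$secretion)] <- solution$secretion
  # umol * kJ/mol = 1e-6 mol * 1e3 J/mol = 1e-3 J
  sum((fin - fout) * E[mets]) * 1e-3
}

#' Create an energy-audit context
#'
#' Counts, over a run, the FBA solutions whose output carries more free
#' energy than their input (violations) and the share of growth they
#' produced.
#'
#' @param E Energy table from [energy_table()].
#' @param tolerance Violation tolerance in J, absorbing LP round-off.
#' @return An object of class `energy_audit`.
#' @export
energy_audit <- function(E = energy_table(), tolerance = 1e-9) {
  structure(list(E = E, tolerance = tolerance,
                 n_total = 0L, n_violating = 0L,
                 growth_total = 0, growth_violating = 0,
                 total_loss = 0),
            class = "energy_audit")
}

audit_record <- function(audit, solution, dB) {
  l <- energy_balance(solution, audit$E)
  audit$n_total <- audit$n_total + 1L
  audit$growth_total <- audit$growth_total + dB
  audit$total_loss <- audit$total_loss + l
  if (l < -audit$tolerance) {
    audit$n_violating <- audit$n_violating + 1L
    audit$growth_violating <- audit$growth_violating + dB
  }
  audit
}

#' Summarize an energy audit
#'
#' @param audit An `energy_audit` that has recorded at least one solution.
#' @return List with `fraction_plausible` (% of solutions dissipating free
#'   energy) and `violator_growth_share` (% of total growth produced by
#'   flagged solutions).
#' @export
audit_summary <- function(audit) {
  if (audit$n_total == 0) {
    stop("audit error: no FBA solutions recorded; summary undefined")
  }
  list(
    n_solutions = audit$n_total,
    fraction_plausible = 100 * (audit$n_total - audit$n_violating) / audit$n_total,
    violator_growth_share = if (audit$growth_total > 0) {
      100 * audit$growth_violating / audit$growth_total
    } else 0
  )
}

#' Write an audit report as JSON
#'
#' @param audit An `energy_audit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(audit, path) {
  jsonlite::write_json(audit_summary(audit), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
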