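# Enzymatically constrained FBA: per population per timestep, maximize flux
# through the ATP objective subject to internal steady state, irreversible
# fluxes, dynamic uptake bounds set by local metabolite availability, and a
# cap on summed flux that scales with population size.

FLUX_CLIP <- 1e-12 # post-hoc zeroing of numerically tiny fluxes

#' Dynamic uptake bounds from local metabolite availability
#'
#' The upper bound on the uptake flux of metabolite *i* is `c_i / B_u`
#' (amount at the site divided by population units), so that the total
#' amount taken up by the site's single population cannot exceed what is
#' present. Metabolites in the `unlimited` set (water) are unbounded;
#' metabolites absent from `env` are bounded at zero.
#'
#' @param env Named numeric vector of site amounts (umol).
#' @param B_u Population size in population units (cells / 1e10).
#' @param metabolites Metabolites to bound (defaults to `names(env)`).
#' @param unlimited Metabolites with infinite supply.
#' @return Named numeric vector of bounds (umol per timestep per unit).
#' @export
uptake_bounds <- function(env, B_u, metabolites = names(env),
                          unlimited = "h2o(e)") {
  stopifnot(B_u > 0)
  if (any(env < 0)) {
    stop("internal-consistency error: negative environment amount(s): ",
         paste(names(env)[env < 0], collapse = ", "))
  }
  b <- setNames(rep(0, length(metabolites)), metabolites)
  have <- intersect(metabolites, names(env))
  b[have] <- env[have] / B_u
  b[metabolites %in% unlimited] <- Inf
  b
}

# Precompute the static LP structure of a model so the per-timestep solve
# only updates the uptake bounds. Cached on the gem.
gem_lp_template <- function(gem, constraint_scope = "all_but_objective",
                            unlimited = "h2o(e)") {
  cached <- gem$lp_template
  if (!is.null(cached) && identical(cached$scope, constraint_scope) &&
      identical(cached$unlimited, unlimited)) {
    return(cached)
  }
  rids <- gem$reactions$id
  n <- length(rids)
  S <- as.matrix(gem$S)
  obj <- as.numeric(rids == gem$objective)
  capsel <- switch(constraint_scope,
    all_but_objective = as.numeric(rids != gem$objective),
    internal = as.numeric(!gem$reactions$is_exchange),
    all = rep(1, n),
    stop("unknown constraint_scope '", constraint_scope, "'")
  )
  ex <- gem$exchange_index
  up_ok <- !is.na(ex$uptake)
  sec_ok <- !is.na(ex$secretion)
  tpl <- list(
    scope = constraint_scope, unlimited = unlimited,
    n = n, rids = rids, S = S, obj = obj, capsel = capsel,
    static_ub = unname(gem$ub[rids]),
    static_lb = unname(gem$lb[rids]),
    uptake_cols = match(ex$uptake[up_ok], rids),
    uptake_mets = ex$metabolite[up_ok],
    uptake_unlimited = ex$metabolite[up_ok] %in% unlimited,
    secretion_cols = match(ex$secretion[sec_ok], rids),
    secretion_mets = ex$metabolite[sec_ok]
  )
  # can the model produce ATP from the unlimited metabolites alone? if not,
  # sites with no substrate can skip the LP entirely
  ub0 <- tpl$static_ub
  ub0[tpl$uptake_cols[!tpl$uptake_unlimited]] <- 0
  sol0 <- .fba_solve_cpp(tpl$S, tpl$obj, tpl$capsel, 1, ub0, FALSE)
  tpl$grows_on_unlimited <- sol0$status == 0 && sol0$objective > 1e-9
  tpl
}

#' Solve the enzymatically constrained FBA problem of one population
#'
#' Maximizes flux through the model's ATP objective subject to
#' `S f = 0`, `f >= 0`, the summed-flux enzymatic constraint
#' `sum(f) <= a`, and uptake bounds from [uptake_bounds()]. Among degenerate
#' optima, a secondary LP minimizes total flux at the fixed optimum
#' (parsimonious choice), making exchange fluxes deterministic.
#'
#' @param gem A [gem_model()].
#' @param env Named numeric vector of metabolite amounts at the site (umol).
#' @param B Population size in cells.
#' @param a Enzymatic constraint, umol total flux per timestep per
#'   population unit (Table-2 default 2).
#' @param unlimited Metabolites treated as infinitely available.
#' @param constraint_scope Which reactions the summed-flux cap covers:
#'   `"all_but_objective"` (default; every irreversible reaction except the
#'   ATP demand pseudo-reaction), `"internal"`, or `"all"`.
#' @param parsimonious Resolve degenerate optima by minimizing total flux.
#' @param template Precomputed LP template (internal use).
#' @return An object of class `fba_solution`: list with `fluxes` (named,
#'   umol/step/unit), `uptake` and `secretion` (named per-metabolite
#'   exchange fluxes), `atp_flux` (objective value), and `status`
#'   (`"optimal"`, `"zero"`, or `"infeasible"`).
#' @export
solve_fba <- function(gem, env, B, a = 2, unlimited = "h2o(e)",
                      constraint_scope = "all_but_objective",
                      parsimonious = TRUE, template = NULL) {
  stopifnot(B > 0, a > 0)
  tpl <- template %||% gem_lp_template(gem, constraint_scope, unlimited)
  B_u <- B / POP_UNIT_CELLS
  if (any(env < 0)) {
    stop("internal-consistency error: negative environment amount(s): ",
         paste(names(env)[env < 0], collapse = ", "))
  }

  avail <- rep(0, length(tpl$uptake_mets))
  have <- match(tpl$uptake_mets, names(env))
  ok <- !is.na(have)
  avail[ok] <- env[have[ok]]
  bound <- avail / B_u
  bound[tpl$uptake_unlimited] <- Inf

  if (!tpl$grows_on_unlimited && all(bound[!tpl$uptake_unlimited] < FLUX_CLIP)) {
    return(zero_solution(tpl))
  }

  ub <- tpl$static_ub
  ub[tpl$uptake_cols] <- pmin(ub[tpl$uptake_cols], bound)
  # bounds at or above the summed-flux cap cannot bind for capped reactions
  redundant <- tpl$capsel > 0 & is.finite(ub) & ub >= a
  ub[redundant] <- Inf

  sol <- .fba_solve_cpp(tpl$S, tpl$obj, tpl$capsel, a, ub, parsimonious)
  if (sol$status != 0) {
    out <- zero_solution(tpl)
    out$status <- "infeasible"
    return(out)
  }
  f <- sol$x
  f[f < FLUX_CLIP] <- 0
  names(f) <- tpl$rids
  up <- setNames(f[tpl$uptake_cols], tpl$uptake_mets)
  sec <- setNames(f[tpl$secretion_cols], tpl$secretion_mets)
  atp <- max(0, sol$objective)
  structure(
    list(fluxes = f, uptake = up, secretion = sec,
         atp_flux = if (atp < FLUX_CLIP) 0 else atp,
         status = if (all(f == 0)) "zero" else "optimal"),
    class = "fba_solution"
  )
}

zero_solution <- function(tpl) {
  structure(
    list(fluxes = setNames(rep(0, tpl$n), tpl$rids),
         uptake = setNames(rep(0, length(tpl$uptake_mets)), tpl$uptake_mets),
         secretion = setNames(rep(0, length(tpl$secretion_mets)), tpl$secretion_mets),
         atp_flux = 0, status = "zero"),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status:", x$status,
      " ATP flux:", format(x$atp_flux), "umol/step/unit\n")
  invisible(x)
}

#' Population growth from ATP production
#'
#' Populations grow linearly with the rate of ATP production: the ATP flux
#' (umol per timestep per population unit) is converted to moles, scaled by
#' the population's size in units (`B / 1e10` cells), and divided by the
#' ATP needed to grow one cell (Table-2 default `1e-15` mol), giving the
#' cell increment of one forward-Euler timestep.
#'
#' @param atp_flux ATP flux, umol per timestep per population unit.
#' @param B Population size in cells.
#' @param atp_per_cell ATP to grow one cell, mol.
#' @return Cell increment for one timestep.
#' @export
growth_from_atp <- function(atp_flux, B, atp_per_cell = 1e-15) {
  stopifnot(all(atp_flux >= 0))
  atp_flux * 1e-6 * (B / POP_UNIT_CELLS) / atp_per_cell
}
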