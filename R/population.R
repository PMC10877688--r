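# Metapopulation dynamics: initialization, per-site metabolism, growth,
# spreading, quiescence, stochastic death, colonization, Kawasaki-style
# mixing, and distal washout. At most one population occupies a site.

#' Bundle GEMs into a community roster
#'
#' Precomputes the LP template of every model so per-timestep solves only
#' update uptake bounds.
#'
#' @param gems Named list of [gem_model()] objects (names = species ids).
#' @param constraint_scope,unlimited Passed to the FBA layer.
#' @return An object of class `community_roster`.
#' @export
community_roster <- function(gems, constraint_scope = "all_but_objective",
                             unlimited = "h2o(e)") {
  stopifnot(length(gems) >= 1)
  if (is.null(names(gems))) {
    names(gems) <- vapply(gems, function(g) g$species_id, character(1))
  }
  templates <- lapply(gems, gem_lp_template,
                      constraint_scope = constraint_scope, unlimited = unlimited)
  structure(list(gems = gems, templates = templates,
                 species = names(gems)), class = "community_roster")
}

#' Exchangeable metabolites of a roster
#'
#' @param roster A [community_roster()].
#' @return Character vector: union of all environment-coupled exchange
#'   metabolites over the roster.
#' @export
roster_metabolites <- function(roster) {
  sort(unique(unlist(lapply(roster$gems, function(g) g$exchange_index$metabolite))))
}

new_community_state <- function(lattice, species = integer(), B = numeric(),
                                col = integer(), row = integer()) {
  occ <- matrix(0L, lattice$width, lattice$height)
  if (length(species)) occ[cbind(col, row)] <- seq_along(species)
  structure(
    list(lattice = lattice, species = as.integer(species), B = B,
         col = as.integer(col), row = as.integer(row),
         quiescent = rep(FALSE, length(species)), occ = occ, t = 0L),
    class = "community_state"
  )
}

# drop populations by index, keeping the occupancy matrix consistent
state_drop <- function(state, drop_idx) {
  if (!length(drop_idx)) return(state)
  keep <- setdiff(seq_along(state$B), drop_idx)
  state$species <- state$species[keep]
  state$B <- state$B[keep]
  state$col <- state$col[keep]
  state$row <- state$row[keep]
  state$quiescent <- state$quiescent[keep]
  state$occ[] <- 0L
  if (length(keep)) state$occ[cbind(state$col, state$row)] <- seq_along(keep)
  state
}

#' Initialize a community
#'
#' Each lattice site is independently occupied with probability `p` by a
#' population of `size` cells of a uniformly random roster species
#' (on the default lattice this averages around 540 populations and a total
#' initial load of 2.7e10 cells).
#'
#' @param roster A [community_roster()].
#' @param lattice A [lattice_geometry()].
#' @param p Occupancy probability per site.
#' @param size Initial population size, cells.
#' @return An object of class `community_state`.
#' @export
initialize_community <- function(roster, lattice, p = 0.3, size = 5e7) {
  stopifnot(p >= 0, p <= 1, size > 0)
  w <- lattice$width; h <- lattice$height
  hit <- which(runif(w * h) < p)
  n <- length(hit)
  sp <- if (n) sample.int(length(roster$species), n, replace = TRUE) else integer()
  new_community_state(lattice,
                      species = sp, B = rep(size, n),
                      col = ((hit - 1) %% w) + 1L,
                      row = ((hit - 1) %/% w) + 1L)
}

#' Population table
#'
#' @param state A `community_state`.
#' @param roster Optional [community_roster()] to translate species indices
#'   to ids.
#' @return Tibble (t, column, row, species, B, quiescent), ordered by
#'   column then row.
#' @export
population_table <- function(state, roster = NULL) {
  sp <- if (is.null(roster)) as.character(state$species) else
    roster$species[state$species]
  ord <- order(state$col, state$row)
  tibble::tibble(t = state$t, column = state$col[ord], row = state$row[ord],
                 species = sp[ord], B = state$B[ord],
                 quiescent = state$quiescent[ord])
}

#' Run metabolism for every population
#'
#' For each non-quiescent population, in uniformly random order, solves the
#' enzymatically constrained FBA problem against its site's metabolite
#' amounts, withdraws the uptaken amounts from and deposits the secreted
#' amounts into the site pool, and applies ATP-proportional growth (capped
#' at `max_size`). Quiescent populations are skipped. Infeasible solves
#' leave the population and its site untouched.
#'
#' @param state A `community_state`.
#' @param field A [metabolite_field()].
#' @param roster A [community_roster()].
#' @param a Enzymatic constraint (umol flux per timestep per unit).
#' @param max_size Maximum population size, cells.
#' @param atp_per_cell ATP to grow one cell, mol.
#' @param audit Optional energy-audit context from [energy_audit()];
#'   updated observationally (never affects the trajectory).
#' @param record If `TRUE`, return per-species exchange totals.
#' @return List with `state`, `field`, `growth` (total cell increment),
#'   `audit`, and (if recording) `uptake`/`secretion` matrices
#'   (species x metabolite, umol).
#' @export
metabolize_all <- function(state, field, roster, a = 2, max_size = 2e10,
                           atp_per_cell = 1e-15, audit = NULL, record = TRUE) {
  n <- length(state$B)
  mets <- dimnames(field$amounts)[[1]]
  nsp <- length(roster$species)
  up_tot <- if (record) matrix(0, nsp, length(mets),
                               dimnames = list(roster$species, mets)) else NULL
  sec_tot <- if (record) up_tot else NULL
  growth <- 0
  if (n) {
    for (i in sample.int(n)) {
      if (state$quiescent[i]) next
      sp <- state$species[i]
      tpl <- roster$templates[[sp]]
      env <- field$amounts[, state$col[i], state$row[i]]
      sol <- solve_fba(roster$gems[[sp]], env, state$B[i], a = a,
                       template = tpl)
      if (sol$status == "infeasible") next
      B_u <- state$B[i] / POP_UNIT_CELLS
      if (sol$status == "optimal") {
        env2 <- env
        if (length(sol$uptake)) {
          env2[names(sol$uptake)] <- env2[names(sol$uptake)] - sol$uptake * B_u
          # guard against LP round-off overdraw
          env2[env2 < 0] <- 0
        }
        if (length(sol$secretion)) {
          env2[names(sol$secretion)] <- env2[names(sol$secretion)] +
            sol$secretion * B_u
        }
        field$amounts[, state$col[i], state$row[i]] <- env2
        dB <- growth_from_atp(sol$atp_flux, state$B[i], atp_per_cell)
        dB <- min(dB, max_size - state$B[i])
        state$B[i] <- state$B[i] + dB
        growth <- growth + dB
        if (record) {
          up_tot[sp, names(sol$uptake)] <- up_tot[sp, names(sol$uptake)] +
            sol$uptake * B_u
          sec_tot[sp, names(sol$secretion)] <- sec_tot[sp, names(sol$secretion)] +
            sol$secretion * B_u
        }
        if (!is.null(audit)) audit <- audit_record(audit, sol, dB)
      } else if (!is.null(audit)) {
        audit <- audit_record(audit, sol, 0)
      }
    }
  }
  list(state = state, field = field, growth = growth, audit = audit,
       uptake = up_tot, secretion = sec_tot)
}

moore_neighbors <- function(col, row, w, h) {
  dc <- rep(-1:1, times = 3); dr <- rep(-1:1, each = 3)
  keep <- !(dc == 0 & dr == 0)
  nc <- col + dc[keep]; nr <- row + dr[keep]
  ok <- nc >= 1 & nc <= w & nr >= 1 & nr <= h
  cbind(nc[ok], nr[ok])
}

#' Spread large populations into empty neighbouring sites
#'
#' Every population of at least `threshold` cells with at least one empty
#' Moore-neighbourhood site splits: a uniformly chosen empty neighbour
#' receives a new population of the same species holding half the cells;
#' total cells are conserved. Populations are processed in random order.
#'
#' @param state A `community_state`.
#' @param threshold Population size needed to create a new population.
#' @return The updated state.
#' @export
spread <- function(state, threshold = 1e10) {
  n <- length(state$B)
  if (!n) return(state)
  w <- state$lattice$width; h <- state$lattice$height
  for (i in sample.int(n)) {
    if (state$B[i] < threshold) next
    nb <- moore_neighbors(state$col[i], state$row[i], w, h)
    empty <- nb[state$occ[nb] == 0L, , drop = FALSE]
    if (!nrow(empty)) next
    pick <- empty[sample.int(nrow(empty), 1), ]
    half <- state$B[i] / 2
    state$B[i] <- half
    state$species <- c(state$species, state$species[i])
    state$B <- c(state$B, half)
    state$col <- c(state$col, pick[1])
    state$row <- c(state$row, pick[2])
    state$quiescent <- c(state$quiescent, FALSE)
    state$occ[pick[1], pick[2]] <- length(state$B)
  }
  state
}

#' Update quiescence flags
#'
#' Populations at or above the maximum size stop performing metabolism;
#' they still die, swap and resume once below the threshold. With
#' `enabled = FALSE` (sensitivity variant) no population is ever quiescent.
#'
#' @param state A `community_state`.
#' @param max_size Maximum population size, cells.
#' @param enabled Quiescence on/off.
#' @return The updated state.
#' @export
update_quiescence <- function(state, max_size = 2e10, enabled = TRUE) {
  state$quiescent <- if (enabled) state$B >= max_size else
    rep(FALSE, length(state$B))
  state
}

#' Random population death
#'
#' Each population is independently removed with probability `p` per
#' timestep; its biomass is not returned to the metabolite pools.
#'
#' @param state A `community_state`.
#' @param p Death probability per population per timestep.
#' @return The updated state with attribute `"died_B"` (cells removed).
#' @export
die <- function(state, p = 0.0075) {
  n <- length(state$B)
  if (!n || p <= 0) { attr(state, "died_B") <- 0; return(state) }
  dead <- which(runif(n) < p)
  died_B <- sum(state$B[dead])
  state <- state_drop(state, dead)
  attr(state, "died_B") <- died_B
  state
}

#' Colonization of empty sites
#'
#' Each empty lattice site gains, with probability `p` per timestep, a new
#' population of `size` cells of a uniformly random roster species
#' (representing crypt reservoirs and ingested bacteria).
#'
#' @param state A `community_state`.
#' @param roster A [community_roster()].
#' @param p Colonization probability per empty site per timestep.
#' @param size New population size, cells.
#' @return The updated state with attribute `"colonized"` (count).
#' @export
colonize <- function(state, roster, p = 5e-5, size = 5e7) {
  empty <- which(state$occ == 0L)
  if (!length(empty) || p <= 0) { attr(state, "colonized") <- 0L; return(state) }
  hit <- empty[runif(length(empty)) < p]
  for (idx in hit) {
    w <- state$lattice$width
    cc <- ((idx - 1) %% w) + 1L
    rr <- ((idx - 1) %/% w) + 1L
    state$species <- c(state$species,
                       sample.int(length(roster$species), 1))
    state$B <- c(state$B, size)
    state$col <- c(state$col, cc)
    state$row <- c(state$row, rr)
    state$quiescent <- c(state$quiescent, FALSE)
    state$occ[cc, rr] <- length(state$B)
  }
  attr(state, "colonized") <- length(hit)
  state
}

#' Kawasaki-style mixing of populations
#'
#' In random site order, each site's full content (population or emptiness)
#' swaps with a uniformly chosen Moore-neighbourhood site, provided neither
#' partner has already swapped in this pass. `repeats = 5` is the fast
#' sensitivity variant; `fraction = 0.2` limits a pass to a fifth of the
#' sites (slow variant). The resulting population diffusion matches the
#' metabolite diffusion coefficient.
#'
#' @param state A `community_state`.
#' @param repeats Passes per timestep.
#' @param fraction Fraction of sites attempting a swap per pass.
#' @return The updated state.
#' @export
mix_populations <- function(state, repeats = 1, fraction = 1) {
  if (!length(state$B)) return(state)
  occ <- .kawasaki_pass_cpp(state$occ, as.integer(repeats), fraction)
  pos <- which(occ != 0L)
  idx <- occ[pos]
  w <- state$lattice$width
  state$col[idx] <- as.integer(((pos - 1) %% w) + 1L)
  state$row[idx] <- as.integer(((pos - 1) %/% w) + 1L)
  state$occ <- occ
  state
}

#' Assign all populations to random non-overlapping sites (well-mixed mode)
#'
#' @param state A `community_state`.
#' @return The updated state.
#' @export
well_mixed_shuffle <- function(state) {
  n <- length(state$B)
  if (!n) return(state)
  w <- state$lattice$width; h <- state$lattice$height
  pos <- sample.int(w * h, n)
  state$col <- as.integer(((pos - 1) %% w) + 1L)
  state$row <- as.integer(((pos - 1) %/% w) + 1L)
  state$occ[] <- 0L
  state$occ[cbind(state$col, state$row)] <- seq_len(n)
  state
}

#' Remove populations at the most distal column
#'
#' @param state A `community_state`.
#' @return The updated state with attribute `"removed_B"` (cells washed
#'   out).
#' @export
remove_distal_populations <- function(state) {
  drop_idx <- which(state$col == state$lattice$width)
  removed_B <- sum(state$B[drop_idx])
  state <- state_drop(state, drop_idx)
  attr(state, "removed_B") <- removed_B
  state
}
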