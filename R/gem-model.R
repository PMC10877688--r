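# Internal representation of a genome-scale metabolic model (GEM) and its
# normalization: all reactions irreversible, exchange/sink/demand reactions
# classified, stoichiometric matrix S assembled.

#' Construct a normalized GEM from raw reaction specifications
#'
#' Raw reactions may be reversible (negative lower bound); they are split
#' into two irreversible reactions (the reverse direction gets the suffix
#' `_rev` and negated stoichiometry) so that all fluxes are nonnegative.
#' Reactions whose id starts with one of `exchange_prefixes` are recorded as
#' exchange reactions; those touching a single extracellular `"(e)"`
#' metabolite are coupled to the environment and indexed by metabolite with
#' their uptake and secretion directions.
#'
#' @param species_id Identifier of the (sub)species the model describes.
#' @param reactions List of raw reactions, each a list with elements `id`,
#'   `stoich` (named numeric, negative = consumed), `lb`, `ub` and
#'   optionally `source` (`"gem"` or `"patch"`).
#' @param objective Id of the reaction whose flux FBA maximizes (the ATP
#'   demand/production reaction).
#' @param exchange_prefixes Id prefixes marking exchange/sink/demand
#'   reactions (AGORA convention).
#' @param exchange_override Additional reaction ids to treat as exchange.
#' @param boundary_mets Metabolite ids excluded from the steady-state
#'   constraint (boundary species).
#' @return An object of class `gem_model`.
#' @export
gem_model <- function(species_id, reactions, objective,
                      exchange_prefixes = c("EX_", "sink_", "DM_"),
                      exchange_override = character(),
                      boundary_mets = character()) {
  stopifnot(is.character(species_id), length(species_id) == 1)
  if (length(reactions) == 0) {
    stop("gem parse error: model '", species_id, "' contains no reactions")
  }
  split <- normalize_reactions(reactions)
  gem <- structure(
    list(
      species_id = species_id,
      stoich = split$stoich,
      lb = split$lb,
      ub = split$ub,
      source = split$source,
      objective = objective,
      exchange_prefixes = exchange_prefixes,
      exchange_override = exchange_override,
      boundary_mets = boundary_mets
    ),
    class = "gem_model"
  )
  gem_rebuild(gem)
}

# Split reversible raw reactions into irreversible pairs.
normalize_reactions <- function(reactions) {
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("gem parse error: duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stoich <- list(); lb <- c(); ub <- c(); source <- c()
  for (r in reactions) {
    if (length(r$stoich) == 0) {
      stop("gem parse error: reaction '", r$id, "' has empty stoichiometry")
    }
    r_lb <- if (is.null(r$lb)) 0 else r$lb
    r_ub <- if (is.null(r$ub)) 1000 else r$ub
    src <- if (is.null(r$source)) "gem" else r$source
    if (r_ub < 0) {
      stop("gem parse error: reaction '", r$id, "' has negative upper bound")
    }
    stoich[[r$id]] <- r$stoich
    lb[r$id] <- max(0, r_lb)
    ub[r$id] <- r_ub
    source[r$id] <- src
    if (r_lb < 0) {
      rid <- paste0(r$id, "_rev")
      stoich[[rid]] <- -r$stoich
      lb[rid] <- 0
      ub[rid] <- -r_lb
      source[rid] <- src
    }
  }
  list(stoich = stoich, lb = lb, ub = ub, source = source)
}

# Recompute the derived pieces (metabolite set, S, reaction table, exchange
# index) after construction or patching; validates invariants.
gem_rebuild <- function(gem) {
  rids <- names(gem$stoich)
  mets <- sort(unique(unlist(lapply(gem$stoich, names), use.names = FALSE)))
  ss_mets <- setdiff(mets, gem$boundary_mets)

  is_exchange <- grepl(paste0("^(", paste(gem$exchange_prefixes, collapse = "|"), ")"),
                       rids, ignore.case = TRUE) | rids %in% gem$exchange_override

  env_coupled <- logical(length(rids))
  ex_met <- character(length(rids))
  for (k in which(is_exchange)) {
    s <- gem$stoich[[k]]
    if (length(s) != 1) {
      stop("gem parse error: exchange reaction '", rids[k],
           "' must touch exactly one metabolite")
    }
    ex_met[k] <- names(s)
    env_coupled[k] <- grepl("\\(e\\)$", names(s))
  }

  # index environment-coupled exchanges by metabolite; positive stoichiometry
  # after splitting means the reaction delivers the metabolite to the model
  # (= uptake from the environment), negative means secretion into it
  idx <- which(env_coupled)
  ex_tbl <- NULL
  if (length(idx)) {
    met <- ex_met[idx]
    dirn <- vapply(idx, function(k) unname(gem$stoich[[k]][1]), numeric(1))
    up <- tapply(ifelse(dirn > 0, rids[idx], NA_character_), met,
                 function(x) x[!is.na(x)][1])
    sec <- tapply(ifelse(dirn < 0, rids[idx], NA_character_), met,
                  function(x) x[!is.na(x)][1])
    ex_tbl <- tibble::tibble(
      metabolite = names(up),
      uptake = as.character(up),
      secretion = as.character(sec[names(up)])
    )
  } else {
    ex_tbl <- tibble::tibble(metabolite = character(),
                             uptake = character(), secretion = character())
  }

  if (!gem$objective %in% rids) {
    stop("gem configuration error: objective reaction '", gem$objective,
         "' not found in model '", gem$species_id, "'")
  }

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  met_pos <- setNames(seq_along(ss_mets), ss_mets)
  for (j in seq_along(rids)) {
    s <- gem$stoich[[j]]
    keep <- names(s) %in% ss_mets
    if (any(keep)) {
      trip_i <- c(trip_i, met_pos[names(s)[keep]])
      trip_j <- c(trip_j, rep(j, sum(keep)))
      trip_x <- c(trip_x, unname(s[keep]))
    }
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(ss_mets), length(rids)),
                            dimnames = list(ss_mets, rids))

  gem$mets <- ss_mets
  gem$S <- S
  gem$reactions <- tibble::tibble(
    id = rids,
    lower_bound = unname(gem$lb[rids]),
    upper_bound = unname(gem$ub[rids]),
    is_exchange = is_exchange,
    env_coupled = env_coupled,
    source = unname(gem$source[rids])
  )
  gem$exchange_index <- ex_tbl
  gem$lp_template <- NULL # invalidate cache
  gem
}

#' @export
print.gem_model <- function(x, ...) {
  cat("<gem_model> ", x$species_id, "\n",
      "  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n",
      "  metabolites: ", length(x$mets), "\n",
      "  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Tidy the reaction table of a GEM
#'
#' @param x A `gem_model`.
#' @param ... Unused.
#' @return A tibble with one row per (irreversible) reaction.
#' @export
tidy.gem_model <- function(x, ...) x$reactions
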