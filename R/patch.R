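# Declarative patches to GEMs: add/remove reactions, set bounds, block
# uptake. Used for model curation and for the knockout experiments in which
# the uptake of lactose, lactate or 1,2-propanediol by selected species is
# disabled.

#' Create a model patch
#'
#' A patch is an ordered list of actions applied to one species' GEM.
#' Actions are built with [patch_add_reaction()], [patch_remove_reaction()],
#' [patch_set_bound()] and [patch_block_uptake()].
#'
#' @param target_species Species id the patch applies to.
#' @param actions List of patch actions.
#' @return An object of class `model_patch`.
#' @export
model_patch <- function(target_species, actions = list()) {
  structure(list(target_species = target_species, actions = actions),
            class = "model_patch")
}

#' @rdname model_patch
#' @param id Reaction id.
#' @param stoich Named numeric stoichiometry (negative = consumed).
#' @param lb,ub Flux bounds; a negative `lb` marks a reversible reaction
#'   that will be split on application.
#' @export
patch_add_reaction <- function(id, stoich, lb = 0, ub = 1000) {
  list(verb = "add_reaction", id = id, stoich = stoich, lb = lb, ub = ub)
}

#' @rdname model_patch
#' @export
patch_remove_reaction <- function(id) list(verb = "remove_reaction", id = id)

#' @rdname model_patch
#' @param lower,upper New bounds (post-normalization, so `lower >= 0`).
#' @export
patch_set_bound <- function(id, lower, upper) {
  list(verb = "set_bound", id = id, lower = lower, upper = upper)
}

#' @rdname model_patch
#' @param metabolite Extracellular metabolite id, e.g. `"lcts(e)"`; the
#'   uptake direction of its exchange reaction is bounded to zero.
#' @export
patch_block_uptake <- function(metabolite) {
  list(verb = "block_uptake", metabolite = metabolite)
}

#' Apply a patch to a GEM
#'
#' Applies the patch actions in order and returns a new model; the input
#' model is unchanged (patching is pure, hence idempotent in outcome when
#' reapplied to the same base model).
#'
#' @param gem A [gem_model()].
#' @param patch A [model_patch()] whose `target_species` matches the model.
#' @return A new `gem_model`.
#' @export
apply_patch <- function(gem, patch) {
  stopifnot(inherits(gem, "gem_model"), inherits(patch, "model_patch"))
  if (!identical(patch$target_species, gem$species_id)) {
    stop("patch error: patch targets '", patch$target_species,
         "' but model is '", gem$species_id, "'")
  }
  for (act in patch$actions) {
    gem <- switch(act$verb,
      add_reaction = {
        if (act$id %in% names(gem$stoich)) {
          stop("patch error: reaction '", act$id, "' already exists")
        }
        split <- normalize_reactions(list(list(id = act$id, stoich = act$stoich,
                                               lb = act$lb, ub = act$ub,
                                               source = "patch")))
        gem$stoich <- c(gem$stoich, split$stoich)
        gem$lb <- c(gem$lb, split$lb)
        gem$ub <- c(gem$ub, split$ub)
        gem$source <- c(gem$source, split$source)
        gem
      },
      remove_reaction = {
        if (!act$id %in% names(gem$stoich)) {
          stop("patch error: cannot remove unknown reaction '", act$id, "'")
        }
        keep <- setdiff(names(gem$stoich), act$id)
        gem$stoich <- gem$stoich[keep]
        gem$lb <- gem$lb[keep]; gem$ub <- gem$ub[keep]
        gem$source <- gem$source[keep]
        gem
      },
      set_bound = {
        if (!act$id %in% names(gem$stoich)) {
          stop("patch error: cannot set bounds of unknown reaction '", act$id, "'")
        }
        if (act$lower < 0) {
          stop("patch error: lower bound must be >= 0 after normalization")
        }
        gem$lb[act$id] <- act$lower
        gem$ub[act$id] <- act$upper
        gem$source[act$id] <- "patch"
        gem
      },
      block_uptake = {
        row <- which(gem$exchange_index$metabolite == act$metabolite)
        if (!length(row)) {
          stop("patch error: no exchange for metabolite '", act$metabolite, "'")
        }
        up <- gem$exchange_index$uptake[row[1]]
        if (!is.na(up)) {
          gem$lb[up] <- 0
          gem$ub[up] <- 0
          gem$source[up] <- "patch"
        }
        gem
      },
      stop("patch error: unknown action verb '", act$verb, "'")
    )
    # keep the exchange index current so later actions can refer to it
    gem <- gem_rebuild(gem)
  }
  gem
}

#' Read a patch from a YAML or JSON document
#'
#' The document has fields `target_species` and `actions`, each action an
#' object with a `verb` (`add_reaction`, `remove_reaction`, `set_bound`,
#' `block_uptake`) and the verb's fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [model_patch()].
#' @export
read_patch <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  actions <- lapply(raw$actions, function(a) {
    switch(a$verb,
      add_reaction = patch_add_reaction(a$id, unlist(a$stoich),
                                        lb = a$lb %||% 0, ub = a$ub %||% 1000),
      remove_reaction = patch_remove_reaction(a$id),
      set_bound = patch_set_bound(a$id, a$lower, a$upper),
      block_uptake = patch_block_uptake(a$metabolite),
      stop("patch error: unknown action verb '", a$verb, "'")
    )
  })
  model_patch(raw$target_species, actions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default metabolite ids used by the prebiotic pathway patches
#'
#' @return Named list of AGORA-dialect ids (without compartment suffix).
#' @export
default_met_ids <- function() {
  list(lactose = "lcts", fucose = "fuc", galactose = "gal",
       water = "h2o", atp = "atp", fl2 = "2fl",
       dp3 = "gos_dp3", dp4 = "gos_dp4", dp5 = "gos_dp5")
}

#' Add prebiotic digestion pathways to a GEM
#'
#' Equips the designated prebiotic consumer (in the infant gut,
#' *B. longum* ssp. *infantis*) with digestion of 2'-fucosyllactose or
#' galacto-oligosaccharides.
#'
#' For `"2FL"`: an exchange for extracellular 2'-FL, an ABC transporter
#' importing it at an ATP cost, and an intracellular fucosidase splitting it
#' into lactose and fucose. For `"GOS"`: exchanges for the DP3/DP4/DP5
#' fractions, extracellular stepwise cleavage DP5 -> DP4 + galactose and
#' DP4 -> DP3 + galactose, ABC transport of DP3 at an ATP cost, and
#' intracellular hydrolysis of DP3 into lactose and galactose. Cleavage
#' products released extracellularly appear in the consumer's own site pool
#' (they do not diffuse during digestion).
#'
#' @param gem A [gem_model()] that already contains the lactose metabolite
#'   and (for `"2FL"`) fucose or (for `"GOS"`) galactose.
#' @param which `"2FL"` or `"GOS"`.
#' @param atp_cost ATP consumed per molecule transported by the ABC
#'   transporter (default 1).
#' @param ids Metabolite id configuration, see [default_met_ids()].
#' @return A patched `gem_model`.
#' @export
add_prebiotic_pathways <- function(gem, which = c("2FL", "GOS"),
                                   atp_cost = 1, ids = default_met_ids()) {
  which <- match.arg(which)
  ec <- function(x) paste0(x, "(e)")
  ic <- function(x) paste0(x, "(c)")
  all_mets <- unique(unlist(lapply(gem$stoich, names), use.names = FALSE))
  need <- c(ic(ids$lactose),
            if (which == "2FL") ic(ids$fucose) else ic(ids$galactose))
  missing <- setdiff(need, all_mets)
  if (length(missing)) {
    stop("patch error: model '", gem$species_id,
         "' lacks prerequisite metabolite(s): ", paste(missing, collapse = ", "))
  }
  acts <- list()
  add_ex <- function(met) {
    rid <- paste0("EX_", met)
    if (!rid %in% names(gem$stoich)) {
      acts[[length(acts) + 1]] <<-
        patch_add_reaction(rid, setNames(-1, met), lb = -1000, ub = 1000)
    }
  }
  if (which == "2FL") {
    fl <- ids$fl2
    add_ex(ec(fl))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("ABCt_", fl),
      setNames(c(-1, -atp_cost, 1), c(ec(fl), ic(ids$atp), ic(fl))))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("FUCSD_", fl),
      setNames(c(-1, 1, 1), c(ic(fl), ic(ids$lactose), ic(ids$fucose))))
  } else {
    dp3 <- ids$dp3; dp4 <- ids$dp4; dp5 <- ids$dp5
    add_ex(ec(dp5)); add_ex(ec(dp4)); add_ex(ec(dp3)); add_ex(ec(ids$galactose))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("GOSCLV_", dp5),
      setNames(c(-1, 1, 1), c(ec(dp5), ec(dp4), ec(ids$galactose))))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("GOSCLV_", dp4),
      setNames(c(-1, 1, 1), c(ec(dp4), ec(dp3), ec(ids$galactose))))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("ABCt_", dp3),
      setNames(c(-1, -atp_cost, 1), c(ec(dp3), ic(ids$atp), ic(dp3))))
    acts[[length(acts) + 1]] <- patch_add_reaction(
      paste0("GOSHYD_", dp3),
      setNames(c(-1, 1, 1), c(ic(dp3), ic(ids$lactose), ic(ids$galactose))))
  }
  apply_patch(gem, model_patch(gem$species_id, acts))
}

#' Check elemental balance of a GEM's internal reactions
#'
#' Computes the net carbon (and optionally hydrogen/oxygen) content of each
#' non-exchange reaction from a composition table. Virtual bookkeeping
#' metabolites (ATP by default) are ignored; hydrogen/oxygen imbalances
#' equal to an integer number of water molecules are tolerated, reflecting
#' the water-of-condensation convention of the hydrolysis reactions.
#'
#' @param gem A [gem_model()].
#' @param composition A composition table from [composition_table()].
#' @param virtual Metabolite ids (compartment-free) ignored in the balance.
#' @return Tibble with one row per non-exchange reaction and the net C, H,
#'   O change (positive = created).
#' @export
element_balance <- function(gem, composition = composition_table(),
                            virtual = "atp") {
  strip <- function(m) sub("\\([ec]\\)$", "", m)
  rows <- list()
  for (rid in names(gem$stoich)) {
    if (gem$reactions$is_exchange[match(rid, gem$reactions$id)]) next
    s <- gem$stoich[[rid]]
    base <- strip(names(s))
    keep <- !(base %in% virtual)
    s <- s[keep]; base <- base[keep]
    if (!length(s)) next
    unknown <- setdiff(base, composition$metabolite)
    if (length(unknown)) {
      stop("composition table lacks metabolite(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    comp <- composition[match(base, composition$metabolite), ]
    rows[[rid]] <- tibble::tibble(
      id = rid,
      dC = sum(s * comp$C), dH = sum(s * comp$H), dO = sum(s * comp$O))
  }
  out <- dplyr::bind_rows(rows)
  out$water_balanced <- abs(out$dC) < 1e-9 &
    abs(out$dH - 2 * round(out$dH / 2)) < 1e-9 &
    abs(out$dO - out$dH / 2) < 1e-9
  out
}
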