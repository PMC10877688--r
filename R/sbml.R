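# SBML I/O for AGORA-dialect models (SBML Level 3 with the fbc package).
# Metabolite and reaction ids follow the AGORA/BiGG text dialect with
# "(e)"/"(c)" compartment suffixes; in SBML ids the parentheses are encoded
# as "__40__"/"__41__" and ids carry the conventional "M_"/"R_" prefixes.

encode_sbml_id <- function(x, prefix) {
  paste0(prefix, gsub("\\)", "__41__", gsub("\\(", "__40__", x)))
}

decode_sbml_id <- function(x) {
  x <- sub("^[MR]_", "", x)
  gsub("__41__", ")", gsub("__40__", "(", x))
}

met_compartment <- function(met) {
  ifelse(grepl("\\(e\\)$", met), "e", "c")
}

#' Write a raw model to SBML
#'
#' Serializes a raw (possibly reversible) model specification to SBML Level
#' 3 with fbc-style flux bounds and objective, in the AGORA id dialect, so
#' generated fixtures exercise the same reader as downloaded models.
#'
#' @param raw A list with elements `id` (model id), `reactions` (list of
#'   lists with `id`, `stoich`, `lb`, `ub`) and `objective` (reaction id).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gem_sbml <- function(raw, path) {
  mets <- sort(unique(unlist(lapply(raw$reactions, function(r) names(r$stoich)))))
  bounds <- unique(unlist(lapply(raw$reactions, function(r) {
    c(if (is.null(r$lb)) 0 else r$lb, if (is.null(r$ub)) 1000 else r$ub)
  })))
  bound_id <- function(v) paste0("bnd_", gsub("[^0-9a-zA-Z]", "_", format(v, trim = TRUE)))

  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc,
    level = "3", version = "1", "fbc:required" = "false"
  )
  model <- xml2::xml_add_child(doc, "model", id = raw$id, "fbc:strict" = "true")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in c("c", "e")) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in mets) {
    xml2::xml_add_child(spl, "species",
      id = encode_sbml_id(m, "M_"),
      compartment = met_compartment(m),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
  }
  pl <- xml2::xml_add_child(model, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(pl, "parameter", id = bound_id(v),
                        value = format(v, trim = TRUE), constant = "true")
  }
  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (r in raw$reactions) {
    lb <- if (is.null(r$lb)) 0 else r$lb
    ub <- if (is.null(r$ub)) 1000 else r$ub
    rn <- xml2::xml_add_child(rl, "reaction",
      id = encode_sbml_id(r$id, "R_"),
      reversible = if (lb < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bound_id(lb),
      "fbc:upperFluxBound" = bound_id(ub))
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lrn <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(lrn, "speciesReference",
          species = encode_sbml_id(m, "M_"),
          stoichiometry = format(-reac[[m]], trim = TRUE), constant = "true")
      }
    }
    if (length(prod)) {
      lpn <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lpn, "speciesReference",
          species = encode_sbml_id(m, "M_"),
          stoichiometry = format(prod[[m]], trim = TRUE), constant = "true")
      }
    }
  }
  if (!is.null(raw$objective)) {
    ol <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fl, "fbc:fluxObjective",
                        "fbc:reaction" = encode_sbml_id(raw$objective, "R_"),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

attr_like <- function(attrs, suffix) {
  hit <- grep(paste0("(^|:)", suffix, "$"), names(attrs))
  if (length(hit)) attrs[[hit[1]]] else NA_character_
}

#' Load a genome-scale metabolic model from SBML
#'
#' Reads an SBML document in the AGORA dialect, splits reversible reactions
#' into irreversible pairs, classifies exchange/sink/demand reactions by id
#' prefix, and assembles the stoichiometric matrix.
#'
#' @param path Path to an SBML file.
#' @param species_id Species identifier to attach; defaults to the SBML
#'   model id.
#' @param objective Objective reaction id (decoded dialect, e.g.
#'   `"DM_atp(c)"`). If `NULL`, the fbc active objective is used, then the
#'   conventional ATP demand ids; an error is raised if none is found.
#' @param exchange_prefixes,exchange_override,boundary_mets Passed to
#'   [gem_model()].
#' @return A [gem_model()] object.
#' @export
load_gem <- function(path, species_id = NULL, objective = NULL,
                     exchange_prefixes = c("EX_", "sink_", "DM_"),
                     exchange_override = character(),
                     boundary_mets = character()) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    stop("SBML parse error: no <model> element in '", path, "'")
  }
  if (is.null(species_id)) species_id <- xml2::xml_attr(model, "id")

  boundary_species <- character()
  for (sp in xml2::xml_find_all(model, ".//listOfSpecies/species")) {
    if (identical(xml2::xml_attr(sp, "boundaryCondition"), "true")) {
      boundary_species <- c(boundary_species, decode_sbml_id(xml2::xml_attr(sp, "id")))
    }
  }

  params <- list()
  for (p in xml2::xml_find_all(model, ".//listOfParameters/parameter")) {
    params[[xml2::xml_attr(p, "id")]] <- as.numeric(xml2::xml_attr(p, "value"))
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) {
    stop("SBML parse error: model '", species_id, "' declares zero reactions")
  }
  reactions <- vector("list", length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    rn <- rx_nodes[[k]]
    attrs <- as.list(xml2::xml_attrs(rn))
    rid <- decode_sbml_id(attrs$id)
    reversible <- identical(attrs$reversible, "true")
    stoich <- c()
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sr, "stoichiometry")
      stoich[decode_sbml_id(xml2::xml_attr(sr, "species"))] <-
        -(if (is.na(s)) 1 else as.numeric(s))
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sr, "stoichiometry")
      m <- decode_sbml_id(xml2::xml_attr(sr, "species"))
      prev <- if (m %in% names(stoich)) stoich[[m]] else 0
      stoich[m] <- prev + (if (is.na(s)) 1 else as.numeric(s))
    }
    if (length(stoich) == 0) {
      stop("SBML parse error: reaction '", rid, "' has no participants")
    }
    lb_ref <- attr_like(attrs, "lowerFluxBound")
    ub_ref <- attr_like(attrs, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && !is.null(params[[lb_ref]])) params[[lb_ref]] else NA_real_
    ub <- if (!is.na(ub_ref) && !is.null(params[[ub_ref]])) params[[ub_ref]] else NA_real_
    # kineticLaw-style local bound parameters (older AGORA exports)
    if (is.na(lb)) {
      lp <- xml2::xml_find_first(rn, ".//parameter[@id='LOWER_BOUND']")
      if (!inherits(lp, "xml_missing")) lb <- as.numeric(xml2::xml_attr(lp, "value"))
    }
    if (is.na(ub)) {
      up <- xml2::xml_find_first(rn, ".//parameter[@id='UPPER_BOUND']")
      if (!inherits(up, "xml_missing")) ub <- as.numeric(xml2::xml_attr(up, "value"))
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    reactions[[k]] <- list(id = rid, stoich = stoich, lb = lb, ub = ub)
  }

  if (is.null(objective)) {
    fo <- xml2::xml_find_first(model, ".//fluxObjective")
    if (!inherits(fo, "xml_missing")) {
      objective <- decode_sbml_id(attr_like(as.list(xml2::xml_attrs(fo)), "reaction"))
    }
  }
  if (is.null(objective)) {
    rids <- vapply(reactions, `[[`, character(1), "id")
    guess <- intersect(c("DM_atp(c)", "ATPM", "DM_atp[c]"), rids)
    if (length(guess)) objective <- guess[1]
  }
  if (is.null(objective)) {
    stop("gem configuration error: no identifiable ATP objective in '",
         species_id, "'; pass `objective`")
  }

  gem_model(species_id, reactions, objective,
            exchange_prefixes = exchange_prefixes,
            exchange_override = exchange_override,
            boundary_mets = union(boundary_mets, boundary_species))
}
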