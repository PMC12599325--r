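#' Read / write a stoichiometric model (JSON)
#'
#' Plain-text model exchange format: a JSON object with `id`,
#' `metabolites` (array of `{id, carbon}`), `reactions` (array of
#' `{id, stoich: {metabolite: coefficient}, lb, ub}`), `biomass`,
#' `supplied_source`, and optionally `biomass_metabolite`. Files with
#' extension `.xml` or `.sbml` are read as SBML level 3 with the `fbc`
#' package instead (see [read_sbml_model()]).
#'
#' @param path File path.
#' @return A `"metabolic_model"`.
#' @export
read_metabolic_model <- function(path) {
  stopifnot(file.exists(path))
  if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) {
    return(read_sbml_model(path))
  }
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(j$metabolites, function(m) m$id, character(1)),
    carbon = vapply(j$metabolites, function(m) as.numeric(m$carbon),
                    numeric(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(j$reactions, function(r) {
    list(id = r$id, stoich = unlist(r$stoich),
         lb = r$lb %||% 0, ub = r$ub %||% 1000)
  })
  metabolic_model(mets, rxns, biomass = j$biomass,
                  supplied_source = j$supplied_source,
                  biomass_metabolite = j$biomass_metabolite,
                  id = j$id %||% "model")
}

#' @param model A `"metabolic_model"` to write.
#' @rdname read_metabolic_model
#' @export
write_metabolic_model <- function(model, path) {
  rxns <- lapply(model$reaction_ids, function(r) {
    st <- model$S[, r]
    st <- st[st != 0]
    list(id = r, stoich = as.list(st),
         lb = unname(model$lb[r]), ub = unname(model$ub[r]))
  })
  obj <- list(id = model$id,
              metabolites = lapply(seq_len(nrow(model$metabolites)),
                function(i) list(id = model$metabolites$id[i],
                                 carbon = model$metabolites$carbon[i])),
              reactions = rxns,
              biomass = model$biomass,
              supplied_source = model$supplied_source)
  if (!is.null(model$biomass_metabolite)) {
    obj$biomass_metabolite <- model$biomass_metabolite
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# carbon atoms from a chemical formula like "C6H12O6" or "CHO2"
carbon_count_from_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    nn <- sub("^[A-Za-z]+", "", tk)
    if (el == "C") total <- total + if (nzchar(nn)) as.numeric(nn) else 1
  }
  total
}

#' Read an SBML level 3 / fbc model
#'
#' Minimal importer for the subset of SBML level 3 with the `fbc`
#' extension needed here: species (carbon counts parsed from
#' `fbc:chemicalFormula`), reactions with stoichiometries and flux
#' bounds resolved from the parameter list, and the active objective.
#' The supplied carbon source is not part of SBML and must be given.
#'
#' @param path Path to the SBML file.
#' @param supplied_source Metabolite id of the supplied carbon source;
#'   when `NULL`, taken as the single metabolite of the first exchange
#'   reaction with a positive upper bound.
#' @return A `"metabolic_model"`.
#' @export
read_sbml_model <- function(path, supplied_source = NULL) {
  doc <- xml2::read_xml(path)
  mod <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  sp_nodes <- xml2::xml_find_all(
    mod, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    carbon = vapply(sp_nodes, function(nd) {
      f <- xml2::xml_attr(nd, "chemicalFormula")
      carbon_count_from_formula(f)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  par_nodes <- xml2::xml_find_all(
    mod, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(
    mod, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    refs <- function(kind, sgn) {
      rr <- xml2::xml_find_all(
        nd, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                    kind))
      st <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(rr, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    st <- tapply(st, names(st), sum)
    lbp <- xml2::xml_attr(nd, "lowerFluxBound")
    ubp <- xml2::xml_attr(nd, "upperFluxBound")
    list(id = id, stoich = stats::setNames(as.numeric(st), names(st)),
         lb = if (!is.na(lbp)) unname(par_val[lbp]) else 0,
         ub = if (!is.na(ubp)) unname(par_val[ubp]) else 1000)
  })
  obj_node <- xml2::xml_find_first(
    mod, ".//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  if (inherits(obj_node, "xml_missing")) {
    stop("SBML model declares no flux objective")
  }
  biomass <- xml2::xml_attr(obj_node, "reaction")
  if (is.null(supplied_source)) {
    one_met <- vapply(rxns, function(r) length(r$stoich) == 1L, logical(1))
    pos_ub <- vapply(rxns, function(r) r$ub > 0, logical(1))
    cand <- which(one_met & pos_ub &
                    vapply(rxns, function(r) r$id, character(1)) != biomass)
    if (!length(cand)) stop("cannot infer the supplied carbon source")
    supplied_source <- names(rxns[[cand[1L]]]$stoich)
  }
  metabolic_model(mets, rxns, biomass = biomass,
                  supplied_source = supplied_source,
                  id = xml2::xml_attr(mod, "id") %||% "sbml_model")
}

#' Toy stoichiometric fixtures
#'
#' Small hand-checkable models used in the documentation and tests:
#' `toy_linear_model()` is a single pathway (uptake of A, conversion to
#' B, biomass from B), `toy_parallel_model()` adds a second A-to-B
#' route with its own capacity, and `toy_branched_model()` has a
#' carbon-free cofactor, a side branch and parallel routes.
#'
#' @param uptake Uptake bound of the supplied source (default 10).
#' @param cap1,cap2 Capacities of the two parallel routes.
#' @return A `"metabolic_model"`.
#' @export
toy_linear_model <- function(uptake = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), carbon = c(6, 6)),
    reactions = list(
      list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = uptake),
      list(id = "r1", stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS", supplied_source = "A", id = "toy_linear")
}

#' @rdname toy_linear_model
#' @export
toy_parallel_model <- function(uptake = 10, cap1 = 10, cap2 = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), carbon = c(6, 6)),
    reactions = list(
      list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = uptake),
      list(id = "r1", stoich = c(A = -1, B = 1), lb = 0, ub = cap1),
      list(id = "r2", stoich = c(A = -1, B = 1), lb = 0, ub = cap2),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS", supplied_source = "A", id = "toy_parallel")
}

#' @rdname toy_linear_model
#' @export
toy_branched_model <- function(uptake = 10) {
  # A -> B -> D -> biomass, with a cofactor-coupled alternative
  # B -> C -> D of capacity 2, and a dead side branch B -> E.
  metabolic_model(
    metabolites = data.frame(
      id = c("A", "B", "C", "D", "E", "cof"),
      carbon = c(6, 6, 3, 3, 2, 0)),
    reactions = list(
      list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = uptake),
      list(id = "v1", stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      list(id = "v2", stoich = c(B = -1, D = 2), lb = 0, ub = 1000),
      list(id = "v3", stoich = c(B = -1, C = 2, cof = 1), lb = 0, ub = 2),
      list(id = "v4", stoich = c(C = -1, D = 1), lb = 0, ub = 1000),
      list(id = "v5", stoich = c(B = -1, E = 1), lb = 0, ub = 1000),
      list(id = "EX_E", stoich = c(E = -1), lb = 0, ub = 1000),
      list(id = "EX_cof", stoich = c(cof = -1), lb = 0, ub = 1000),
      list(id = "BIOMASS", stoich = c(D = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS", supplied_source = "A", id = "toy_branched")
}
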