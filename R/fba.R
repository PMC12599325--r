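#' Construct a stoichiometric model
#'
#' A small constraint-based metabolic model: metabolites with
#' carbon-atom counts, reactions with stoichiometries and flux bounds,
#' a biomass (objective) reaction, and the identity of the supplied
#' carbon source. Exchange reactions are recognised as reactions that
#' touch a single metabolite.
#'
#' @param metabolites Data frame with columns `id` and `carbon`
#'   (carbon atoms, >= 0).
#' @param reactions List of reactions, each a list with `id`,
#'   `stoich` (named numeric: metabolite coefficients, negative =
#'   consumed), `lb`, `ub`.
#' @param biomass Reaction id of the biomass objective.
#' @param supplied_source Metabolite id of the supplied carbon source.
#' @param biomass_metabolite Optional id of a biomass pseudo-metabolite
#'   to exclude from by-product counts.
#' @param id Model identifier (default `"model"`).
#' @return An object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, biomass,
                            supplied_source, biomass_metabolite = NULL,
                            id = "model") {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "carbon") %in% names(metabolites)))
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (any(metabolites$carbon < 0)) stop("negative carbon count")
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  if (!(biomass %in% rxn_ids)) stop("biomass reaction not found")
  if (!(supplied_source %in% metabolites$id)) {
    stop("supplied carbon source is not a declared metabolite")
  }
  S <- matrix(0, nrow = nrow(metabolites), ncol = length(reactions),
              dimnames = list(metabolites$id, rxn_ids))
  lb <- numeric(length(reactions))
  ub <- numeric(length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    st <- r$stoich
    bad <- setdiff(names(st), metabolites$id)
    if (length(bad)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    S[names(st), j] <- st
    lb[j] <- r$lb %||% 0
    ub[j] <- r$ub %||% 1000
    if (lb[j] > ub[j]) stop("reaction '", r$id, "': lower bound > upper")
  }
  exchanges <- rxn_ids[colSums(S != 0) == 1L]
  structure(list(id = id, metabolites = metabolites, S = S,
                 lb = stats::setNames(lb, rxn_ids),
                 ub = stats::setNames(ub, rxn_ids),
                 reaction_ids = rxn_ids, biomass = biomass,
                 supplied_source = supplied_source,
                 biomass_metabolite = biomass_metabolite,
                 exchanges = exchanges),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Stoichiometric model '%s': %d metabolites, %d reactions\n",
              x$id, nrow(x$metabolites), length(x$reaction_ids)))
  cat(sprintf("  biomass reaction: %s; supplied source: %s\n",
              x$biomass, x$supplied_source))
  invisible(x)
}

#' Change the flux bounds of one reaction
#'
#' @param model A `"metabolic_model"`.
#' @param reaction Reaction id.
#' @param lb,ub New bounds.
#' @return The modified model.
#' @export
set_reaction_bounds <- function(model, reaction, lb, ub) {
  if (!(reaction %in% model$reaction_ids)) {
    stop("unknown reaction: ", reaction)
  }
  if (lb > ub) stop("lower bound > upper bound")
  model$lb[reaction] <- lb
  model$ub[reaction] <- ub
  model
}

#' Flux balance analysis
#'
#' Maximises the biomass flux subject to steady state (`S v = 0`) and
#' the flux bounds, by linear programming (a two-phase simplex with
#' Bland's anti-cycling rule, after shifting the fluxes to
#' non-negative coordinates). The optimal biomass value is unique even
#' when the optimal flux vector is not. Infinite bounds are capped at
#' `big` for the solver.
#'
#' @param model A `"metabolic_model"`.
#' @param big Replacement for infinite bounds (default `1e6`).
#' @return List with `status` (`"optimal"` or `"infeasible"`),
#'   `objective` (biomass flux; `NA` when infeasible) and `fluxes`
#'   (named vector).
#' @export
fba_optimize <- function(model, big = 1e6) {
  stopifnot(inherits(model, "metabolic_model"))
  lb <- model$lb
  ub <- model$ub
  ub[!is.finite(ub)] <- big
  lb[!is.finite(lb)] <- -big
  n <- length(lb)
  # shift to w = v - lb >= 0 and eliminate fixed (lb == ub) variables
  rng <- ub - lb
  free <- rng > 0
  rhs_eq <- as.numeric(-model$S %*% lb)
  infeas <- list(status = "infeasible", objective = NA_real_,
                 fluxes = stats::setNames(rep(NA_real_, n),
                                          model$reaction_ids))
  if (!any(free)) {
    if (max(abs(rhs_eq)) > 1e-9) return(infeas)
    v <- lb
    return(list(status = "optimal",
                objective = unname(v[model$reaction_ids == model$biomass]),
                fluxes = stats::setNames(v, model$reaction_ids)))
  }
  obj <- as.numeric(model$reaction_ids == model$biomass)[free]
  sol <- simplex_box_lp(model$S[, free, drop = FALSE], rhs_eq,
                        upper = unname(rng[free]), obj = obj)
  if (sol$status == "infeasible") return(infeas)
  if (sol$status != "optimal") stop("LP is unbounded")
  v <- lb
  v[free] <- sol$x + lb[free]
  list(status = "optimal",
       objective = unname(v[model$reaction_ids == model$biomass]),
       fluxes = stats::setNames(v, model$reaction_ids))
}

#' Reactions essential for near-optimal growth
#'
#' A reaction is essential when constraining its flux to zero lowers
#' the optimal biomass below `(1 - threshold)` of the baseline optimum
#' (or makes the model infeasible). The biomass reaction itself and the
#' exchange reaction(s) of the supplied carbon source are always
#' included. Restricting downstream by-product counts to essential
#' reactions removes the arbitrariness of degenerate optimal flux
#' vectors: essentiality depends only on optimal values.
#'
#' @param model A `"metabolic_model"` with a feasible baseline and
#'   positive biomass.
#' @param threshold Fractional loss defining essentiality (default
#'   0.01, i.e. a drop of more than 1%).
#' @return Character vector of essential reaction ids (empty, with a
#'   warning, when the baseline biomass is zero).
#' @export
essential_for_optimum <- function(model, threshold = 0.01) {
  base <- fba_optimize(model)
  if (base$status != "optimal") stop("baseline FBA is infeasible")
  if (base$objective <= 1e-12) {
    warning("baseline biomass is zero; no essential set")
    return(character(0))
  }
  forced <- c(model$biomass,
              model$exchanges[vapply(model$exchanges, function(r) {
                model$S[model$supplied_source, r] != 0
              }, logical(1))])
  ess <- vapply(model$reaction_ids, function(r) {
    ko <- set_reaction_bounds(model, r, 0, 0)
    opt <- fba_optimize(ko)
    opt$status != "optimal" ||
      opt$objective < (1 - threshold) * base$objective
  }, logical(1))
  sort(unique(c(model$reaction_ids[ess], forced)))
}

#' Count possible carbon-containing metabolic by-products
#'
#' By-products are the metabolites with at least one carbon atom that
#' participate in reactions which both carry nonzero flux in the given
#' FBA solution and are essential for near-optimal growth. The supplied
#' carbon source itself and any biomass pseudo-metabolite are excluded.
#' "Nonzero" uses a tolerance relative to the largest flux magnitude,
#' absorbing solver noise.
#'
#' @param model A `"metabolic_model"`.
#' @param fluxes Named flux vector from [fba_optimize()].
#' @param essential Character vector from [essential_for_optimum()].
#' @param tol Relative flux tolerance (default `1e-9`).
#' @return List with `model_id`, `source`, `byproducts` (sorted ids)
#'   and `count`.
#' @export
count_carbon_byproducts <- function(model, fluxes, essential,
                                    tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  fluxes <- fluxes[model$reaction_ids]
  if (anyNA(fluxes)) stop("flux vector is incomplete")
  cutoff <- tol * max(abs(fluxes), 1e-300)
  active <- model$reaction_ids[abs(fluxes) > cutoff]
  sel <- intersect(active, essential)
  mets <- rownames(model$S)[rowSums(model$S[, sel, drop = FALSE] != 0) > 0]
  carbon <- model$metabolites$carbon[match(mets, model$metabolites$id)]
  mets <- mets[carbon >= 1]
  mets <- setdiff(mets, c(model$supplied_source, model$biomass_metabolite))
  list(model_id = model$id, source = model$supplied_source,
       byproducts = sort(mets), count = length(mets))
}

#' Correlate by-product counts with the environment-average angle rank
#'
#' For each species, the Spearman correlation between its predicted
#' carbon-containing by-product counts across single carbon sources and
#' the rank of the environment-average interaction angle of those
#' sources, restricted to sources where growth was experimentally
#' verified; Benjamini-Hochberg adjustment across species. Species with
#' fewer than `min_points` usable sources, or constant counts, are
#' skipped.
#'
#' @param reports Data frame with columns `species`, `source`, `count`.
#' @param theta_bar_env Data frame with columns `env` (source name) and
#'   `theta_bar`.
#' @param grown Optional data frame with columns `species`, `source`
#'   restricting each species to sources with verified growth.
#' @param fdr False discovery rate (default 0.05).
#' @param min_points Minimum usable sources per species (default 3).
#' @return Data frame: `species`, `n_sources`, `rho`, `p`, `q`,
#'   `skipped`, `reason`.
#' @export
byproduct_theta_correlation <- function(reports, theta_bar_env,
                                        grown = NULL, fdr = 0.05,
                                        min_points = 3L) {
  stopifnot(all(c("species", "source", "count") %in% names(reports)))
  if (!is.null(grown)) {
    keep <- paste(reports$species, reports$source) %in%
      paste(grown$species, grown$source)
    reports <- reports[keep, , drop = FALSE]
  }
  tb <- theta_bar_env$theta_bar[match(reports$source, theta_bar_env$env)]
  reports$theta_rank_src <- rank(theta_bar_env$theta_bar)[
    match(reports$source, theta_bar_env$env)]
  if (anyNA(tb)) stop("by-product sources missing from theta_bar_env")
  rows <- lapply(split(seq_len(nrow(reports)), reports$species),
    function(i) {
      sp <- reports$species[i[1L]]
      if (length(i) < min_points) {
        return(data.frame(species = sp, n_sources = length(i),
                          rho = NA_real_, p = NA_real_, skipped = TRUE,
                          reason = "too few sources",
                          stringsAsFactors = FALSE))
      }
      if (stats::sd(reports$count[i]) == 0) {
        return(data.frame(species = sp, n_sources = length(i),
                          rho = NA_real_, p = NA_real_, skipped = TRUE,
                          reason = "constant counts",
                          stringsAsFactors = FALSE))
      }
      st <- spearman_trend(reports$theta_rank_src[i], reports$count[i])
      data.frame(species = sp, n_sources = length(i), rho = st$rho,
                 p = st$p, skipped = FALSE, reason = "",
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !out$skipped
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}
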