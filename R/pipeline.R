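#' Run the full co-culture interaction analysis
#'
#' Orchestrates every stage on one dataset: detection-floor handling
#' and yield summaries; unidirectional ratio tests with one
#' Benjamini-Hochberg family and six-class interaction calls; log2
#' effect pairs and interaction angles with per-environment and
#' per-pair averages; the mixing-effect comparisons; grower /
#' non-grower stratification with class enrichment; and the
#' community-level statistics (Monte-Carlo chi-square heterogeneity by
#' carbon source and by pair, pairwise PERMANOVA over biochemical
#' categories when the single-source environments are named after
#' catalogued sources, species rank enrichment, and the
#' carbon-number/theta trend test). All randomised stages derive their
#' seeds from the configuration's master seed, so the whole bundle is
#' reproducible.
#'
#' @param culture A culture table (see [read_culture_table()]); it is
#'   validated and floored here.
#' @param envs An environment table covering every environment in
#'   `culture`.
#' @param config A [coculture_config()].
#' @return An object of class `"coculture_pipeline"`: a list with
#'   `yields`, `tests`, `classes`, `types`, `theta_env`, `theta_pair`,
#'   `mixing`, `growth`, `grower_fractions`, `strata`, `enrichment`,
#'   `community` (chi-square, PERMANOVA, rank enrichment, trend),
#'   `notes`, `config` and `manifest`.
#' @export
run_coculture_pipeline <- function(culture, envs,
                                   config = coculture_config()) {
  stopifnot(inherits(config, "coculture_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  culture <- stage("validate", validate_culture_table(culture))
  missing_env <- setdiff(unique(culture$env), envs$env)
  if (length(missing_env)) {
    stop("stage 'validate': environments absent from the table: ",
         paste(missing_env, collapse = ", "))
  }
  floored <- apply_detection_floor(culture, config$detection_floor)
  yields <- stage("yields", summarize_yields(floored))
  calls <- stage("interaction calls",
                 classify_interactions(floored, config$fdr))
  types <- stage("interaction types",
                 interaction_types(floored, config$detection_floor))
  theta_env <- stage("theta averages",
                     average_theta(types, "environment"))
  single_envs <- envs$env[envs$n_sources == 1L]
  theta_pair <- NULL
  if (any(types$env %in% single_envs)) {
    theta_pair <- stage("theta averages",
                        average_theta(types, "pair", single_envs))
  }
  notes <- character(0)

  mixing <- NULL
  if (any(envs$n_sources >= 2L)) {
    mixing <- stage("mixing analysis",
                    mixing_report(floored, envs, config$fdr,
                                  config$welch))
  } else {
    notes <- c(notes, "no mixture environments: mixing analysis skipped")
  }

  growth <- stage("growth calls",
                  growth_calls(floored, "species",
                               config$detection_floor))
  fractions <- stage("growth calls",
                     grower_fraction_by_carbon_number(growth, envs))
  strata <- stage("stratification",
                  stratify_interactions(calls$classes, growth, envs))
  bins <- intersect(c(1L, 2L, 4L), strata$records$n_sources)
  enrichment <- stage("class enrichment",
                      class_enrichment(strata, config$fdr,
                                       if (length(bins)) bins else NULL))

  community <- list()
  single_classes <- calls$classes[calls$classes$env %in% single_envs, ,
                                  drop = FALSE]
  community$chisq_by_source <- tryCatch(
    chisq_mc(class_count_table(single_classes, "environment"),
             config$chisq_iterations,
             derive_seed(config$seed, "chisq-by-source")),
    error = function(e) {
      notes <<- c(notes, paste("chi-square by source skipped:",
                               conditionMessage(e)))
      NULL
    })
  community$chisq_by_pair <- tryCatch(
    chisq_mc(class_count_table(single_classes, "pair"),
             config$chisq_iterations,
             derive_seed(config$seed, "chisq-by-pair")),
    error = function(e) {
      notes <<- c(notes, paste("chi-square by pair skipped:",
                               conditionMessage(e)))
      NULL
    })
  community$permanova <- NULL
  if (all(single_envs %in% carbon_sources()$source) &&
      length(single_envs) >= 4L) {
    sub <- types[types$env %in% single_envs, , drop = FALSE]
    pair_id <- paste(sub$species_i, sub$species_j, sep = "-")
    tm <- stats::xtabs(theta ~ env + pair_id, data =
                         cbind(sub, pair_id = pair_id))
    tm <- matrix(as.numeric(tm), nrow = nrow(tm),
                 dimnames = dimnames(tm))
    community$permanova <- tryCatch(
      pairwise_permanova(tm, carbon_sources(),
                         config$permanova_permutations,
                         config$seed, config$fdr,
                         config$exhaustive_limit),
      error = function(e) {
        notes <<- c(notes, paste("PERMANOVA skipped:",
                                 conditionMessage(e)))
        NULL
      })
  } else {
    notes <- c(notes,
               "single-source environments not catalogued: PERMANOVA skipped")
  }
  community$rank_enrichment <- NULL
  if (!is.null(theta_pair) && nrow(theta_pair) >= 2L) {
    community$rank_enrichment <- stage(
      "rank enrichment",
      species_rank_enrichment(
        data.frame(species_i = theta_pair$species_i,
                   species_j = theta_pair$species_j,
                   theta = theta_pair$theta_bar,
                   stringsAsFactors = FALSE),
        config$enrichment_permutations, config$seed, config$fdr,
        config$exhaustive_limit))
  }
  grown_types <- types[envs$n_sources[match(types$env, envs$env)] > 0, ,
                       drop = FALSE]
  community$diversity_trend <- tryCatch(
    spearman_trend(envs$n_sources[match(grown_types$env, envs$env)],
                   grown_types$theta),
    error = function(e) {
      notes <<- c(notes, paste("diversity trend skipped:",
                               conditionMessage(e)))
      NULL
    })

  out <- list(
    yields = yields, tests = calls$tests, classes = calls$classes,
    types = types, theta_env = theta_env, theta_pair = theta_pair,
    mixing = mixing, growth = growth, grower_fractions = fractions,
    strata = strata, enrichment = enrichment, community = community,
    notes = notes, config = config,
    manifest = list(
      package = "cocultr",
      package_version = as.character(utils::packageVersion("cocultr")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed, fdr = config$fdr,
      detection_floor = config$detection_floor,
      mixing_test = if (config$welch) "welch" else "student"))
  class(out) <- "coculture_pipeline"
  out
}

#' @export
print.coculture_pipeline <- function(x, ...) {
  cat("Co-culture interaction analysis\n")
  cat(sprintf("  %d interactions (%d pairs x %d environments)\n",
              nrow(x$classes),
              length(unique(paste(x$classes$species_i,
                                  x$classes$species_j))),
              length(unique(x$classes$env))))
  tab <- table(factor(x$classes$class,
                      levels = interaction_class_levels()))
  cat("  classes: ",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$community$diversity_trend) &&
      !is.na(x$community$diversity_trend$rho)) {
    cat(sprintf("  carbon-number vs theta: Spearman rho = %.3f (p = %.3g)\n",
                x$community$diversity_trend$rho,
                x$community$diversity_trend$p))
  }
  cat(sprintf("  seed %d, FDR %g\n", x$config$seed, x$config$fdr))
  invisible(x)
}

#' @export
summary.coculture_pipeline <- function(object, ...) {
  x <- object
  cat("Interaction class composition by carbon-source number:\n")
  ns <- x$strata$records$n_sources
  print(table(n_sources = ns,
              class = factor(x$strata$records$class,
                             levels = interaction_class_levels())))
  agg <- aggregate_classes(x$classes$class)
  cat("\nAggregate composition: ",
      paste(sprintf("%s %.1f%%", levels(agg),
                    100 * as.numeric(table(agg)) / length(agg)),
            collapse = ", "), "\n")
  if (!is.null(x$theta_env)) {
    cat("\nMost competitive environment: ",
        x$theta_env$env[which.min(x$theta_env$theta_bar)],
        sprintf(" (theta_bar = %.1f deg)",
                min(x$theta_env$theta_bar)), "\n", sep = "")
    cat("Most synergistic environment: ",
        x$theta_env$env[which.max(x$theta_env$theta_bar)],
        sprintf(" (theta_bar = %.1f deg)",
                max(x$theta_env$theta_bar)), "\n", sep = "")
  }
  if (!is.null(x$mixing$fractions)) {
    cat("\nMixture growth vs component average:\n")
    print(x$mixing$fractions, row.names = FALSE)
  }
  if (length(x$notes)) {
    cat("\nNotes:\n")
    for (n in x$notes) cat("  -", n, "\n")
  }
  invisible(x)
}

#' Scatter of effect pairs coloured by interaction class
#'
#' Plots `(min(E_ij, E_ji), max(E_ij, E_ji))` for every pair and
#' environment, the diagonal `max = min` bounding the admissible
#' half-plane and the anti-diagonal `max = -min` from which the angle
#' theta is measured.
#'
#' @param x A `"coculture_pipeline"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coculture_pipeline <- function(x, ...) {
  key <- paste(x$types$species_i, x$types$species_j, x$types$env)
  ckey <- paste(x$classes$species_i, x$classes$species_j,
                x$classes$env)
  cls <- x$classes$class[match(key, ckey)]
  pal <- c(mutualism = "#1b9e77", commensalism = "#66c2a5",
           exploitation = "#7570b3", neutralism = "grey60",
           amensalism = "#fc8d62", competition = "#d95f02")
  lim <- range(c(x$types$coord_min, x$types$coord_max, 0))
  graphics::plot(x$types$coord_min, x$types$coord_max,
                 col = pal[cls], pch = 16, xlim = lim, ylim = lim,
                 xlab = "min(E_ij, E_ji) [log2]",
                 ylab = "max(E_ij, E_ji) [log2]", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::abline(0, -1, lty = 2)
  graphics::legend("topleft", legend = names(pal), col = pal,
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write every report table of a pipeline run
#'
#' Tidy CSV tables plus a JSON manifest recording versions, the seed
#' and the FDR.
#'
#' @param x A `"coculture_pipeline"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_reports <- function(x, dir) {
  stopifnot(inherits(x, "coculture_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(x$tests, "unidirectional_tests")
  wr(x$classes, "interaction_classes")
  wr(x$types, "interaction_types")
  wr(x$theta_env, "theta_by_environment")
  wr(x$theta_pair, "theta_by_pair")
  if (!is.null(x$mixing)) {
    wr(x$mixing$comparisons, "mixing_comparisons")
    wr(x$mixing$fractions, "mixing_fractions")
  }
  wr(x$growth, "growth_calls")
  wr(x$grower_fractions, "grower_fractions")
  wr(x$strata$counts, "stratum_class_counts")
  wr(x$enrichment, "class_enrichment")
  if (!is.null(x$community$permanova)) {
    wr(x$community$permanova, "pairwise_permanova")
  }
  if (!is.null(x$community$rank_enrichment)) {
    wr(x$community$rank_enrichment, "species_rank_enrichment")
  }
  manifest <- x$manifest
  for (nm in c("chisq_by_source", "chisq_by_pair")) {
    if (!is.null(x$community[[nm]])) {
      manifest[[nm]] <- x$community[[nm]][c("statistic", "p",
                                            "iterations")]
    }
  }
  if (!is.null(x$community$diversity_trend)) {
    manifest$diversity_trend <- x$community$diversity_trend
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
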