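#' Construct the component-average pseudo-sample (Group 2)
#'
#' For a species grown on an n-source mixture, the reference
#' distribution is built from its mono-culture summaries on the n
#' component sources: with `m = mean` of the component mean log10
#' yields and `s = sqrt(mean)` of the component unbiased log10
#' variances, the three-point pseudo-sample `{m + s, m, m - s}` has
#' sample mean exactly `m` and unbiased standard deviation exactly `s`.
#'
#' @param mean_log10 Numeric vector: component mean log10 yields.
#' @param var_log10 Numeric vector: component unbiased log10 variances.
#' @return Numeric triple `c(m + s, m, m - s)`.
#' @examples
#' build_group2(c(6, 7), c(0.01, 0.03))
#' @export
build_group2 <- function(mean_log10, var_log10) {
  stopifnot(length(mean_log10) == length(var_log10),
            length(mean_log10) >= 1L)
  if (anyNA(mean_log10) || anyNA(var_log10)) {
    stop("component summaries contain missing values")
  }
  if (any(var_log10 < 0)) stop("negative variance")
  m <- mean(mean_log10)
  s <- sqrt(mean(var_log10))
  c(m + s, m, m - s)
}

#' Compare mixture growth with its component average
#'
#' Two-sample two-sided t-test between Group 1 (the three observed
#' log10 yields in the mixture) and Group 2 (the constructed
#' component-average triple). Welch's unequal-variance test by default.
#' When both samples are exactly constant the test is resolved
#' deterministically: `p = 1` if the means are equal, else `p = 0`.
#'
#' @param group1 Numeric vector of 3 observed log10 yields.
#' @param group2 Numeric triple from [build_group2()].
#' @param welch Use the Welch test (default `TRUE`); `FALSE` pools
#'   variances.
#' @return List with `p`, `direction` (sign of mean(group1) -
#'   mean(group2)), `t`, `df`.
#' @export
compare_mix <- function(group1, group2, welch = TRUE) {
  if (length(group1) != 3L || length(group2) != 3L) {
    stop("both samples must have size 3")
  }
  dir <- sign(mean(group1) - mean(group2))
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    return(list(p = if (mean(group1) == mean(group2)) 1 else 0,
                direction = dir, t = NA_real_, df = NA_real_))
  }
  tt <- stats::t.test(group1, group2, var.equal = !welch,
                      alternative = "two.sided")
  list(p = unname(tt$p.value), direction = dir,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Mixing-effect report for a whole dataset
#'
#' For every (species, mixture environment) with complete component
#' mono-culture summaries, tests whether mixture growth differs from
#' the average of growth on the individual components, adjusts all
#' comparisons as one Benjamini-Hochberg family, and assigns the
#' verdict `higher` / `lower` only when significant, `not_different`
#' otherwise. Mixtures whose component single-source environments are
#' absent are skipped with a logged reason.
#'
#' @param obs A floored culture table (mono-cultures at least).
#' @param envs An environment table covering the mixture and component
#'   environments; component environments are matched as the
#'   single-source environment containing each component.
#' @param fdr False discovery rate (default 0.05).
#' @param welch Welch (default) or pooled-variance t-test.
#' @return List with `comparisons` (species, env, n_components,
#'   group1/group2 values, p, q, verdict), `fractions` (per mixture
#'   size: fraction higher / not_different / lower, and the combined
#'   matched-or-exceeded fraction), and `skipped`.
#' @export
mixing_report <- function(obs, envs, fdr = 0.05, welch = TRUE) {
  yields <- summarize_yields(obs)
  mono <- mono_means(yields)
  src_sets <- environment_sources(envs)
  # map each single source to its single-source environment id
  singles <- envs$env[envs$n_sources == 1L]
  src_of <- vapply(src_sets[singles], identity, character(1))
  env_of_source <- stats::setNames(singles, src_of)

  mixes <- envs$env[envs$n_sources >= 2L]
  species <- sort(unique(mono$focal))
  rows <- list()
  skipped <- list()
  for (mx in mixes) {
    comps <- src_sets[[mx]]
    comp_envs <- env_of_source[comps]
    if (anyNA(comp_envs)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        env = mx, reason = "component single-source environment missing",
        stringsAsFactors = FALSE)
      next
    }
    for (sp in species) {
      reps <- obs$density[obs$focal == sp & is.na(obs$partner) &
                            obs$env == mx]
      if (length(reps) != 3L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          env = mx, reason = sprintf("species '%s': %d mixture replicates",
                                     sp, length(reps)),
          stringsAsFactors = FALSE)
        next
      }
      ml <- lookup_mono(mono, sp, comp_envs, "mean_log10")
      vl <- lookup_mono(mono, sp, comp_envs, "var_log10")
      if (anyNA(ml) || anyNA(vl)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          env = mx, reason = sprintf("species '%s': component summary missing",
                                     sp),
          stringsAsFactors = FALSE)
        next
      }
      g1 <- sort(log10(reps), decreasing = TRUE)
      g2 <- build_group2(ml, vl)
      cm <- compare_mix(g1, g2, welch = welch)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, env = mx, n_components = length(comps),
        group1_1 = g1[1], group1_2 = g1[2], group1_3 = g1[3],
        group2_1 = g2[1], group2_2 = g2[2], group2_3 = g2[3],
        direction = cm$direction, p = cm$p, stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), env = character(0),
               n_components = integer(0), direction = numeric(0),
               p = numeric(0))
  if (nrow(comparisons)) {
    comparisons$q <- stats::p.adjust(comparisons$p, method = "BH")
    sig <- comparisons$q < fdr
    comparisons$verdict <- ifelse(sig & comparisons$direction > 0, "higher",
                                  ifelse(sig & comparisons$direction < 0,
                                         "lower", "not_different"))
  } else {
    comparisons$q <- numeric(0)
    comparisons$verdict <- character(0)
  }
  fractions <- NULL
  if (nrow(comparisons)) {
    sizes <- sort(unique(comparisons$n_components))
    fractions <- do.call(rbind, lapply(sizes, function(n) {
      v <- comparisons$verdict[comparisons$n_components == n]
      data.frame(n_components = n, n_tests = length(v),
                 frac_higher = mean(v == "higher"),
                 frac_not_different = mean(v == "not_different"),
                 frac_lower = mean(v == "lower"),
                 frac_matched_or_exceeded = mean(v != "lower"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(comparisons = comparisons, fractions = fractions,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
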