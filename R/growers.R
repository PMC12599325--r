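#' Grower / non-grower split by Ward's criterion
#'
#' Splits one-dimensional mean log10 yields into two clusters by
#' minimising the total within-cluster sum of squares (Ward's
#' criterion; for 1-D data the optimum is a contiguous split of the
#' sorted values, found exactly). The cluster with the higher mean is
#' labelled `grower`.
#'
#' Degenerate guards: if every value sits at the detection floor the
#' species never grew and all labels are `non_grower`; if the two
#' cluster means are closer than `gap` log10 units there is no real
#' bimodality, and all points take one label decided by comparing the
#' grand mean against `log10(floor) + gap`.
#'
#' @param values Numeric vector (length >= 2) of mean log10 yields.
#' @param floor Detection floor in cells/ml (default `4.57e5`).
#' @param gap Minimum separation (log10 units) between cluster means
#'   for a genuine two-cluster structure; default 0.5.
#' @return Character vector (`"grower"` / `"non_grower"`) aligned with
#'   `values`.
#' @examples
#' ward_growers(c(5.66, 5.7, 8.9, 9.0))
#' @export
ward_growers <- function(values, floor = 4.57e5, gap = 0.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least two values to cluster")
  if (anyNA(values)) stop("missing values")
  lf <- log10(floor)
  if (all(abs(values - lf) <= 1e-9)) {
    return(rep("non_grower", length(values)))
  }
  sp <- ward_split_1d(values)
  hi_is_1 <- mean(values[sp == 1L]) >= mean(values[sp == 2L])
  mean_hi <- mean(values[sp == (if (hi_is_1) 1L else 2L)])
  mean_lo <- mean(values[sp == (if (hi_is_1) 2L else 1L)])
  if (mean_hi - mean_lo < gap) {
    lab <- if (mean(values) > lf + gap) "grower" else "non_grower"
    return(rep(lab, length(values)))
  }
  ifelse((sp == 1L) == hi_is_1, "grower", "non_grower")
}

# Exact 1-D two-cluster Ward split: scan all contiguous splits of the
# sorted values and keep the one with minimal within-cluster SS.
# Returns cluster ids 1/2 in the original order (1 = left/lower block).
ward_split_1d <- function(values) {
  o <- order(values)
  xs <- values[o]
  n <- length(xs)
  wss <- function(x) if (length(x) <= 1L) 0 else sum((x - mean(x))^2)
  crit <- vapply(seq_len(n - 1L), function(k) {
    wss(xs[1:k]) + wss(xs[(k + 1L):n])
  }, numeric(1))
  k <- which.min(crit)
  cl_sorted <- rep(2L, n)
  cl_sorted[seq_len(k)] <- 1L
  cl <- integer(n)
  cl[o] <- cl_sorted
  cl
}

#' Grower / non-grower calls for a dataset
#'
#' Clusters mono-culture mean log10 yields into growers and
#' non-growers. The default axis runs one clustering per species across
#' its environments; the `"source"` axis is the variant that clusters
#' per environment across species.
#'
#' @param obs A floored culture table.
#' @param axis `"species"` (default) or `"source"`.
#' @param floor,gap Passed to [ward_growers()].
#' @return Data frame: `species`, `env`, `mean_log10`, `label`.
#' @export
growth_calls <- function(obs, axis = c("species", "source"),
                         floor = 4.57e5, gap = 0.5) {
  axis <- match.arg(axis)
  mono <- mono_means(summarize_yields(obs))
  if (nrow(mono) == 0L) stop("no mono-culture observations")
  groups <- if (axis == "species") mono$focal else mono$env
  out <- do.call(rbind, lapply(split(seq_len(nrow(mono)), groups),
    function(i) {
      v <- mono$mean_log10[i]
      # a single observation cannot be clustered: threshold it directly
      lab <- if (length(v) < 2L) {
        ifelse(v > log10(floor) + gap, "grower", "non_grower")
      } else {
        ward_growers(v, floor, gap)
      }
      data.frame(species = mono$focal[i], env = mono$env[i],
                 mean_log10 = v, label = lab,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$species, out$env), , drop = FALSE]
}

#' Fraction of growers per carbon-source number
#'
#' @param calls Output of [growth_calls()].
#' @param envs An environment table.
#' @return Data frame: `n_sources`, `n_calls`, `frac_growers`.
#' @export
grower_fraction_by_carbon_number <- function(calls, envs) {
  ns <- envs$n_sources[match(calls$env, envs$env)]
  if (anyNA(ns)) stop("calls reference environments missing from the table")
  out <- do.call(rbind, lapply(sort(unique(ns)), function(n) {
    lab <- calls$label[ns == n]
    data.frame(n_sources = n, n_calls = length(lab),
               frac_growers = mean(lab == "grower"))
  }))
  rownames(out) <- NULL
  out
}

#' Stratify interactions by the growth potential of both species
#'
#' Assigns every (pair, environment) interaction to the
#' `both_growers` stratum when both species are growers in that
#' environment, else to `any_non_grower`, and tabulates class counts
#' per stratum and carbon-source number. Optionally first excludes
#' records where either species' mono-culture mean sits at the
#' detection floor (the sensitivity variant, since inhibition of a
#' species that never grew is undetectable).
#'
#' @param classes The `classes` data frame from
#'   [classify_interactions()].
#' @param calls Output of [growth_calls()].
#' @param envs An environment table.
#' @param exclude_floor_monos Logical (default `FALSE`).
#' @param obs,floor Culture table and floor, required only when
#'   `exclude_floor_monos = TRUE`.
#' @return List with `records` (per-interaction stratum assignment) and
#'   `counts` (stratum x n_sources x class counts).
#' @export
stratify_interactions <- function(classes, calls, envs,
                                  exclude_floor_monos = FALSE,
                                  obs = NULL, floor = 4.57e5) {
  lab <- function(sp, env) {
    i <- match(paste(sp, env, sep = "\r"),
               paste(calls$species, calls$env, sep = "\r"))
    calls$label[i]
  }
  li <- lab(classes$species_i, classes$env)
  lj <- lab(classes$species_j, classes$env)
  if (anyNA(li) || anyNA(lj)) stop("missing growth call for an interaction")
  rec <- classes
  rec$stratum <- ifelse(li == "grower" & lj == "grower",
                        "both_growers", "any_non_grower")
  rec$n_sources <- envs$n_sources[match(rec$env, envs$env)]
  if (anyNA(rec$n_sources)) stop("interaction references unknown environment")
  if (exclude_floor_monos) {
    if (is.null(obs)) stop("obs is required when excluding floored monos")
    mono <- mono_means(summarize_yields(obs))
    mi <- lookup_mono(mono, rec$species_i, rec$env)
    mj <- lookup_mono(mono, rec$species_j, rec$env)
    keep <- mi > floor * (1 + 1e-9) & mj > floor * (1 + 1e-9)
    rec <- rec[keep, , drop = FALSE]
  }
  lv <- interaction_class_levels()
  counts <- as.data.frame(table(
    stratum = rec$stratum,
    n_sources = rec$n_sources,
    class = factor(rec$class, levels = lv)),
    stringsAsFactors = FALSE)
  counts$n_sources <- as.integer(counts$n_sources)
  names(counts)[names(counts) == "Freq"] <- "count"
  list(records = rec, counts = counts)
}

#' Class enrichment within grower strata
#'
#' One-sided hypergeometric (over-representation) test of each
#' interaction class in each stratum against the pooled table,
#' Benjamini-Hochberg adjusted across all (stratum, class) tests.
#' Restricted by default to the carbon-source numbers where both
#' strata exist in the published design (1, 2 and 4).
#'
#' @param strata Output of [stratify_interactions()].
#' @param fdr False discovery rate (default 0.05).
#' @param n_sources_bins Carbon-source numbers pooled into the test
#'   (default `c(1, 2, 4)`); `NULL` uses all.
#' @return Data frame: `stratum`, `class`, `in_stratum`, `stratum_size`,
#'   `in_pool`, `pool_size`, `expected`, `obs_over_exp`, `p`, `q`,
#'   `enriched`.
#' @export
class_enrichment <- function(strata, fdr = 0.05,
                             n_sources_bins = c(1L, 2L, 4L)) {
  rec <- strata$records
  if (!is.null(n_sources_bins)) {
    rec <- rec[rec$n_sources %in% n_sources_bins, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no interactions in the requested bins")
  N <- nrow(rec)
  lv <- interaction_class_levels()
  rows <- list()
  for (st in sort(unique(rec$stratum))) {
    n_st <- sum(rec$stratum == st)
    for (cl in lv) {
      K <- sum(rec$class == cl)
      k <- sum(rec$class == cl & rec$stratum == st)
      p <- if (K == 0L || n_st == 0L || K == N) 1 else
        stats::phyper(k - 1L, K, N - K, n_st, lower.tail = FALSE)
      expd <- n_st * K / N
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, class = cl, in_stratum = k, stratum_size = n_st,
        in_pool = K, pool_size = N, expected = expd,
        obs_over_exp = if (expd > 0) k / expd else NA_real_,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < fdr
  rownames(out) <- NULL
  out
}
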