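#' Class-count table by carbon source or bacterial pair
#'
#' @param classes The `classes` data frame from
#'   [classify_interactions()].
#' @param by `"environment"` (rows = environments) or `"pair"` (rows =
#'   species pairs).
#' @return Integer matrix, rows = grouping levels, columns = the six
#'   interaction classes.
#' @export
class_count_table <- function(classes, by = c("environment", "pair")) {
  by <- match.arg(by)
  g <- if (by == "environment") classes$env else
    paste(classes$species_i, classes$species_j, sep = "-")
  tab <- table(g, factor(classes$class,
                         levels = interaction_class_levels()))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

# Pearson chi-square statistic of a contingency table (no continuity
# correction); cells with zero expectation contribute nothing.
pearson_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- e > 0
  sum((tab[ok] - e[ok])^2 / e[ok])
}

#' Monte-Carlo chi-square heterogeneity test
#'
#' Pearson chi-square statistic of a class-count table, with the null
#' distribution generated by resampling tables with both margins fixed
#' (equivalent to permuting class labels across records), and the
#' add-one estimator `p = (1 + #\{sim >= obs\}) / (1 + iterations)`.
#' Rows and columns with zero totals are dropped with a warning.
#'
#' @param tab Non-negative integer matrix (levels x classes).
#' @param iterations Number of simulated tables (default `1e5`).
#' @param seed Integer seed for the resampling.
#' @return List with `statistic`, `df`, `p`, `iterations`.
#' @export
chisq_mc <- function(tab, iterations = 1e5, seed = 1L) {
  stopifnot(is.matrix(tab), all(tab >= 0), iterations >= 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table must be at least 2x2 after dropping empty margins")
  }
  obs <- pearson_chisq_stat(tab)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sims <- stats::r2dtable(as.integer(iterations), rowSums(tab), colSums(tab))
  stat_sim <- vapply(sims, pearson_chisq_stat, numeric(1))
  p <- (1 + sum(stat_sim >= obs - 1e-12)) / (1 + iterations)
  list(statistic = obs, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       p = p, iterations = as.integer(iterations))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# PERMANOVA pseudo-F for a 2-group partition of a squared-distance
# matrix: F = (SS_between / (k-1)) / (SS_within / (n-k)) with
# SS_total = sum_{i<j} d_ij^2 / n and SS_within summed per group.
permanova_F <- function(d2, grp) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) > 1L) {
      sub <- d2[i, i, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
    }
  }
  ssa <- sst - ssw
  k <- length(unique(grp))
  if (sst < 1e-12) return(0) # no variation at all: no separation
  (ssa / (k - 1)) / (ssw / (n - k))
}

#' Pairwise PERMANOVA over biochemical categories
#'
#' For each pair of carbon-source categories, a permutational
#' multivariate analysis of variance on Euclidean distances between the
#' per-environment theta vectors (environments x pairs), with p-values
#' from permuting the environment category labels (exhaustive
#' enumeration of all label assignments when that is feasible) and
#' Benjamini-Hochberg adjustment across category pairs. Categories with
#' fewer than two environments are skipped with a warning.
#'
#' @param theta_matrix Numeric matrix: rows = single-source
#'   environments (rownames = source names), columns = pairs.
#' @param partition Data frame mapping `source` to `category` (default
#'   [carbon_sources()]).
#' @param permutations Random permutations when enumeration is not
#'   feasible (default 9999).
#' @param seed Integer seed.
#' @param fdr False discovery rate (default 0.05).
#' @param exhaustive_limit Enumerate exactly when the number of label
#'   assignments is at most this (default `2e5`).
#' @return Data frame: `category_1`, `category_2`, `n_1`, `n_2`,
#'   `pseudo_F`, `p`, `q`, `method` (`"exact"` or `"sampled"`).
#' @export
pairwise_permanova <- function(theta_matrix, partition = carbon_sources(),
                               permutations = 9999, seed = 1L, fdr = 0.05,
                               exhaustive_limit = 2e5) {
  stopifnot(is.matrix(theta_matrix), !is.null(rownames(theta_matrix)))
  cat_of <- partition$category[match(rownames(theta_matrix),
                                     partition$source)]
  if (anyNA(cat_of)) {
    stop("environments missing from the category partition: ",
         paste(rownames(theta_matrix)[is.na(cat_of)], collapse = ", "))
  }
  cats <- sort(unique(cat_of))
  sizes <- table(cat_of)
  usable <- names(sizes)[sizes >= 2L]
  if (length(setdiff(cats, usable))) {
    warning("skipping categories with < 2 environments: ",
            paste(setdiff(cats, usable), collapse = ", "))
  }
  if (length(usable) < 2L) stop("need at least two usable categories")
  d2 <- as.matrix(stats::dist(theta_matrix))^2
  combos <- utils::combn(usable, 2L)
  rows <- list()
  for (ci in seq_len(ncol(combos))) {
    c1 <- combos[1L, ci]; c2 <- combos[2L, ci]
    keep <- which(cat_of %in% c(c1, c2))
    grp <- cat_of[keep]
    sub <- d2[keep, keep, drop = FALSE]
    f_obs <- permanova_F(sub, grp)
    n <- length(keep); n1 <- sum(grp == c1)
    n_assign <- choose(n, n1)
    if (n_assign <= exhaustive_limit) {
      sets <- utils::combn(n, n1)
      f_perm <- apply(sets, 2L, function(ix) {
        g <- rep(c2, n); g[ix] <- c1
        permanova_F(sub, g)
      })
      p <- sum(f_perm >= f_obs - 1e-12) / n_assign
      method <- "exact"
    } else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, paste("permanova", c1, c2)))
      f_perm <- vapply(seq_len(permutations), function(b) {
        permanova_F(sub, sample(grp))
      }, numeric(1))
      .Random.seed_restore(old)
      p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
      method <- "sampled"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      category_1 = c1, category_2 = c2, n_1 = n1, n_2 = n - n1,
      pseudo_F = f_obs, p = p, method = method, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Rank-based species enrichment in interaction type
#'
#' Ranks all pairs by their theta value (mid-ranks for ties); for each
#' species the statistic is the mean rank of the pairs containing it.
#' The two-sided p-value comes from the permutation distribution of the
#' mean rank over equally sized random subsets of pairs (exhaustive
#' enumeration when feasible), with Benjamini-Hochberg adjustment
#' across species. A low mean rank marks a species biased toward
#' competitive interactions, a high one toward synergistic.
#'
#' @param pair_theta Data frame with columns `species_i`, `species_j`,
#'   `theta` (one row per pair, e.g. per-pair average theta).
#' @param permutations Random draws when enumeration is not feasible
#'   (default `1e4`).
#' @param seed Integer seed.
#' @param fdr False discovery rate (default 0.05).
#' @param exhaustive_limit Enumerate exactly when `choose(n, k)` is at
#'   most this (default `2e5`).
#' @return Data frame: `species`, `n_pairs`, `mean_rank`,
#'   `expected_rank`, `p`, `q`, `direction`, `method`.
#' @export
species_rank_enrichment <- function(pair_theta, permutations = 1e4,
                                    seed = 1L, fdr = 0.05,
                                    exhaustive_limit = 2e5) {
  stopifnot(all(c("species_i", "species_j", "theta") %in%
                  names(pair_theta)))
  n <- nrow(pair_theta)
  if (n < 2L) stop("need at least two pairs")
  rk <- rank(pair_theta$theta) # mid-ranks for ties
  species <- sort(unique(c(pair_theta$species_i, pair_theta$species_j)))
  rows <- list()
  for (sp in species) {
    member <- pair_theta$species_i == sp | pair_theta$species_j == sp
    k <- sum(member)
    obs <- mean(rk[member])
    if (all(member) || stats::sd(rk) == 0) {
      # every pair contains the species, or all theta tied: no contrast
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, n_pairs = k, mean_rank = obs,
        expected_rank = mean(rk), p = 1, direction = 0,
        method = "degenerate", stringsAsFactors = FALSE)
      next
    }
    if (choose(n, k) <= exhaustive_limit) {
      sets <- utils::combn(n, k)
      dist <- colMeans(matrix(rk[sets], nrow = k))
      p_ge <- mean(dist >= obs - 1e-12)
      p_le <- mean(dist <= obs + 1e-12)
      p <- min(1, 2 * min(p_ge, p_le))
      method <- "exact"
    } else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, paste("rank-enrichment", sp)))
      dist <- vapply(seq_len(permutations), function(b) {
        mean(rk[sample.int(n, k)])
      }, numeric(1))
      .Random.seed_restore(old)
      p_ge <- (1 + sum(dist >= obs - 1e-12)) / (1 + permutations)
      p_le <- (1 + sum(dist <= obs + 1e-12)) / (1 + permutations)
      p <- min(1, 2 * min(p_ge, p_le))
      method <- "sampled"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, n_pairs = k, mean_rank = obs,
      expected_rank = mean(rk), p = p,
      direction = sign(obs - mean(rk)), method = method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spearman rank-correlation trend test
#'
#' Spearman correlation with mid-ranks for ties and a two-sided
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. Constant input leaves the correlation undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3), e.g. carbon-source
#'   counts and theta values.
#' @return List with `rho`, `p`, `n` (`rho` and `p` are `NA` when
#'   either input is constant).
#' @export
spearman_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least three complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}
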