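#' Replicate co-culture/mono-culture yield ratios
#'
#' For a focal species, the ratio of each replicate co-culture density
#' to the mean of its triplicate mono-cultures in the same environment.
#' These ratios carry the unidirectional effect of the partner on the
#' focal species.
#'
#' @param co_reps Numeric vector of replicate co-culture densities.
#' @param mono_mean Mean mono-culture density (must be positive, which
#'   flooring guarantees).
#' @return Numeric vector of ratios.
#' @export
compute_ratios <- function(co_reps, mono_mean) {
  if (!is.numeric(mono_mean) || length(mono_mean) != 1L ||
      !is.finite(mono_mean) || mono_mean <= 0) {
    stop("mono_mean must be a single positive number (flooring violated?)")
  }
  co_reps / mono_mean
}

#' One-sample test of the mean yield ratio against 1
#'
#' Two-sided Student t-test of the null that the mean replicate ratio
#' equals 1 (no effect of the partner), on the raw ratios with
#' `df = n - 1`. Floored triplicates can be exactly constant; that
#' degenerate zero-variance case is resolved deterministically:
#' `p = 1` when the constant equals 1 and `p = 0` otherwise.
#'
#' @param ratios Numeric vector of at least two replicate ratios.
#' @return A list with `mean_ratio`, `t`, `df`, `p`.
#' @examples
#' test_unidirectional(c(1.5, 1.6, 1.4))$p
#' @export
test_unidirectional <- function(ratios) {
  stopifnot(is.numeric(ratios))
  if (length(ratios) < 2L) stop("need at least two replicate ratios")
  m <- mean(ratios)
  s <- stats::sd(ratios)
  n <- length(ratios)
  if (s == 0) {
    return(list(mean_ratio = m, t = NA_real_, df = n - 1L,
                p = if (m == 1) 1 else 0))
  }
  tt <- stats::t.test(ratios, mu = 1, alternative = "two.sided")
  list(mean_ratio = m, t = unname(tt$statistic), df = n - 1L,
       p = unname(tt$p.value))
}

#' Benjamini-Hochberg adjustment and sign calls
#'
#' Adjusts the raw p-values of a whole family of unidirectional tests
#' (both directions, all pairs, all environments of a run) by the
#' Benjamini-Hochberg step-up, then calls each effect: facilitated
#' (`"+"`) when significant with mean ratio above 1, inhibited (`"-"`)
#' when significant with mean ratio below 1, unaffected (`"0"`)
#' otherwise.
#'
#' @param tests Data frame with at least columns `p` and `mean_ratio`.
#' @param fdr False discovery rate (default 0.05).
#' @return The input with columns `q` and `call` added.
#' @export
adjust_and_call <- function(tests, fdr = 0.05) {
  stopifnot(is.data.frame(tests), all(c("p", "mean_ratio") %in% names(tests)))
  if (nrow(tests) == 0L) {
    tests$q <- numeric(0)
    tests$call <- character(0)
    return(tests)
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  sig <- tests$q < fdr
  tests$call <- ifelse(sig & tests$mean_ratio > 1, "+",
                       ifelse(sig & tests$mean_ratio < 1, "-", "0"))
  tests
}

.class_by_calls <- c(
  "+|+" = "mutualism",
  "0|+" = "commensalism",
  "-|+" = "exploitation",
  "0|0" = "neutralism",
  "-|0" = "amensalism",
  "-|-" = "competition"
)

#' Six-class interaction from a pair of sign calls
#'
#' The bidirectional interaction class is determined solely by the
#' unordered pair of unidirectional calls: (+,+) mutualism,
#' (+,0) commensalism, (+,-) exploitation, (0,0) neutralism,
#' (-,0) amensalism, (-,-) competition.
#'
#' @param call_ij,call_ji Sign calls, each in `"+"`, `"0"`, `"-"`
#'   (vectorised).
#' @return Character vector of class names.
#' @examples
#' classify_pair("+", "-")
#' @export
classify_pair <- function(call_ij, call_ji) {
  ok <- c("+", "0", "-")
  if (!all(call_ij %in% ok) || !all(call_ji %in% ok)) {
    stop("calls must be one of '+', '0', '-'")
  }
  # order the two calls canonically as (-, 0, +) so the map is unordered
  r1 <- match(call_ij, c("-", "0", "+"))
  r2 <- match(call_ji, c("-", "0", "+"))
  a <- ifelse(r1 <= r2, call_ij, call_ji)
  b <- ifelse(r1 <= r2, call_ji, call_ij)
  unname(.class_by_calls[paste(a, b, sep = "|")])
}

#' Unidirectional tests and six-class calls for a whole dataset
#'
#' Runs the ratio t-test for every (affected species, partner,
#' environment) present as a co-culture, adjusts all tests as one
#' Benjamini-Hochberg family, and combines the two directions of every
#' pair into its interaction class.
#'
#' @param obs A floored culture table containing mono- and co-cultures.
#' @param fdr False discovery rate (default 0.05).
#' @return A list with `tests` (one row per direction: `affected`,
#'   `partner`, `env`, `n`, `mean_ratio`, `p`, `q`, `call`) and
#'   `classes` (one row per unordered pair and environment: `species_i`,
#'   `species_j`, `env`, `call_ij`, `call_ji`, `q_ij`, `q_ji`, `class`;
#'   `call_ij` is the effect on `species_i`).
#' @export
classify_interactions <- function(obs, fdr = 0.05) {
  yields <- summarize_yields(obs)
  mono <- mono_means(yields)
  co <- obs[!is.na(obs$partner), , drop = FALSE]
  if (nrow(co) == 0L) stop("no co-culture observations")
  key <- paste(co$focal, co$partner, co$env, sep = "\r")
  idx <- split(seq_len(nrow(co)), key)
  rows <- lapply(idx, function(i) {
    aff <- co$focal[i[1L]]
    par <- co$partner[i[1L]]
    env <- co$env[i[1L]]
    mm <- lookup_mono(mono, aff, env)
    if (is.na(mm)) {
      stop(sprintf("missing mono-culture for species '%s' in env '%s'",
                   aff, env))
    }
    tu <- test_unidirectional(compute_ratios(co$density[i], mm))
    data.frame(affected = aff, partner = par, env = env, n = length(i),
               mean_ratio = tu$mean_ratio, p = tu$p,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests <- adjust_and_call(tests, fdr)

  # combine directions: unordered pair keyed by sorted species names
  si <- pmin(tests$affected, tests$partner)
  sj <- pmax(tests$affected, tests$partner)
  pk <- paste(si, sj, tests$env, sep = "\r")
  cls <- lapply(split(seq_len(nrow(tests)), pk), function(i) {
    if (length(i) != 2L) {
      stop("each pair-environment needs both co-culture directions")
    }
    a <- i[which(tests$affected[i] == min(tests$affected[i]))]
    b <- setdiff(i, a)
    data.frame(
      species_i = tests$affected[a], species_j = tests$affected[b],
      env = tests$env[a],
      call_ij = tests$call[a], call_ji = tests$call[b],
      q_ij = tests$q[a], q_ji = tests$q[b],
      class = classify_pair(tests$call[a], tests$call[b]),
      stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, cls)
  rownames(classes) <- NULL
  list(tests = tests,
       classes = classes[order(classes$env, classes$species_i,
                               classes$species_j), , drop = FALSE])
}

#' Aggregate interaction classes
#'
#' Synergistic = mutualism + commensalism; competitive = competition +
#' amensalism; exploitation and neutralism stand alone.
#'
#' @param class Character vector of six-class names.
#' @return Factor with levels `synergistic`, `exploitative`,
#'   `competitive`, `neutral`.
#' @export
aggregate_classes <- function(class) {
  map <- c(mutualism = "synergistic", commensalism = "synergistic",
           exploitation = "exploitative",
           competition = "competitive", amensalism = "competitive",
           neutralism = "neutral")
  bad <- setdiff(unique(class), names(map))
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  factor(unname(map[class]),
         levels = c("synergistic", "exploitative", "competitive", "neutral"))
}

interaction_class_levels <- function() {
  c("mutualism", "commensalism", "exploitation",
    "neutralism", "amensalism", "competition")
}
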