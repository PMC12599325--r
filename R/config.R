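#' Analysis configuration
#'
#' Bundles the constants shared by every stage of the analysis: the
#' detection floor of the cell-density measurement, the false discovery
#' rate used for every Benjamini-Hochberg-corrected test family, the
#' master random seed, and the iteration counts of the Monte-Carlo
#' procedures.
#'
#' @param detection_floor Lower reporting limit of the fluorescent
#'   cell-density measurement, in cells/ml. Densities below it are set to
#'   it before any summary. Default `4.57e5`, the published constant
#'   (derived by the original assay from the 90th percentile of densities
#'   observed without carbon sources; it is treated here as a fixed
#'   constant, not recomputed).
#' @param fdr Target false discovery rate, strictly between 0 and 1,
#'   applied to each test family after Benjamini-Hochberg adjustment.
#'   Default 0.05.
#' @param seed Master integer seed. Each randomised procedure derives a
#'   stable sub-seed from it and the procedure's identity, so stages are
#'   reproducible independently of execution order.
#' @param chisq_iterations Monte-Carlo iterations for the chi-square
#'   heterogeneity tests (default `1e5`).
#' @param permanova_permutations Label permutations per pairwise
#'   PERMANOVA comparison (default 9999); exhaustive enumeration is used
#'   instead whenever it needs at most `exhaustive_limit` evaluations.
#' @param enrichment_permutations Draws for the species rank-enrichment
#'   null (default `1e4`); exhaustive enumeration as above.
#' @param exhaustive_limit Maximum number of arrangements enumerated
#'   exactly before falling back to random sampling.
#' @param welch Logical; use the Welch (unequal-variance) two-sample
#'   t-test in the mixing analysis (default `TRUE`). `FALSE` gives the
#'   pooled-variance Student test.
#' @return An object of class `"coculture_config"` (a named list).
#' @examples
#' cfg <- coculture_config(seed = 7)
#' cfg$detection_floor
#' @export
coculture_config <- function(detection_floor = 4.57e5,
                             fdr = 0.05,
                             seed = 1L,
                             chisq_iterations = 1e5,
                             permanova_permutations = 9999,
                             enrichment_permutations = 1e4,
                             exhaustive_limit = 2e5,
                             welch = TRUE) {
  stopifnot(is.numeric(detection_floor), length(detection_floor) == 1L,
            detection_floor > 0)
  stopifnot(is.numeric(fdr), length(fdr) == 1L, fdr > 0, fdr < 1)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(chisq_iterations >= 1, permanova_permutations >= 1,
            enrichment_permutations >= 1, exhaustive_limit >= 1)
  structure(list(
    detection_floor = detection_floor,
    fdr = fdr,
    seed = as.integer(seed),
    chisq_iterations = as.integer(chisq_iterations),
    permanova_permutations = as.integer(permanova_permutations),
    enrichment_permutations = as.integer(enrichment_permutations),
    exhaustive_limit = as.integer(exhaustive_limit),
    welch = isTRUE(welch)
  ), class = "coculture_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown fields are rejected; missing fields take the
#' [coculture_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match
#'   the arguments of [coculture_config()].
#' @return A `"coculture_config"` object.
#' @export
read_coculture_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(coculture_config))
  bad <- setdiff(names(lst), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(coculture_config, lst)
}

#' @export
print.coculture_config <- function(x, ...) {
  cat("Co-culture analysis configuration\n")
  cat(sprintf("  detection floor : %.3g cells/ml\n", x$detection_floor))
  cat(sprintf("  FDR             : %g\n", x$fdr))
  cat(sprintf("  master seed     : %d\n", x$seed))
  cat(sprintf("  MC iterations   : chisq %d, PERMANOVA %d, enrichment %d\n",
              x$chisq_iterations, x$permanova_permutations,
              x$enrichment_permutations))
  cat(sprintf("  mixing t-test   : %s\n",
              if (x$welch) "Welch" else "Student"))
  invisible(x)
}

# Stable sub-seed from a master seed and a procedure identity string.
# Polynomial string hash mod a Mersenne prime keeps the result a valid
# 32-bit seed and independent of R's RNG state.
derive_seed <- function(master, key) {
  stopifnot(is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
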