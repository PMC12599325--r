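#' Read a culture table
#'
#' One row per replicate endpoint measurement: the focal species, its
#' co-culture partner (empty for mono-cultures), the environment, the
#' replicate index and the fluorescent cell density in cells/ml.
#'
#' @param path Path to a CSV (or TSV, by extension) file with header
#'   columns `focal`, `partner`, `env`, `replicate`, `density`.
#' @return A data frame with those five columns; `partner` is `NA` for
#'   mono-cultures, `density` is numeric and non-negative.
#' @export
read_culture_table <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  validate_culture_table(data.frame(
    focal = df[["focal"]] %||% stop_schema("focal", names(df)),
    partner = df[["partner"]] %||% stop_schema("partner", names(df)),
    env = df[["env"]] %||% stop_schema("env", names(df)),
    replicate = suppressWarnings(as.integer(df[["replicate"]] %||%
      stop_schema("replicate", names(df)))),
    density = suppressWarnings(as.numeric(df[["density"]] %||%
      stop_schema("density", names(df)))),
    stringsAsFactors = FALSE
  ))
}

stop_schema <- function(col, have) {
  stop(sprintf("schema error: missing column '%s' (found: %s)",
               col, paste(have, collapse = ", ")), call. = FALSE)
}

#' Validate a culture table
#'
#' Enforces the measurement contract: densities parse as non-negative
#' reals and no (focal, partner, env, replicate) key occurs twice.
#' Empty-string partners are normalised to `NA` (mono-culture).
#'
#' @param obs A data frame with columns `focal`, `partner`, `env`,
#'   `replicate`, `density`.
#' @return The validated (normalised) data frame.
#' @export
validate_culture_table <- function(obs) {
  need <- c("focal", "partner", "env", "replicate", "density")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  obs$partner[!is.na(obs$partner) & !nzchar(obs$partner)] <- NA_character_
  if (anyNA(obs$density)) stop("validation error: non-numeric density")
  if (any(obs$density < 0)) stop("validation error: negative density")
  if (anyNA(obs$replicate)) stop("validation error: non-integer replicate")
  key <- paste(obs$focal, ifelse(is.na(obs$partner), "", obs$partner),
               obs$env, obs$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (focal, partner, env, replicate)")
  }
  obs[need]
}

#' @param obs A culture table to write.
#' @rdname read_culture_table
#' @export
write_culture_table <- function(obs, path) {
  out <- obs[, c("focal", "partner", "env", "replicate", "density")]
  out$partner[is.na(out$partner)] <- ""
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the detection floor
#'
#' Every density below the lower reporting limit of the assay is set to
#' that limit; a logical `floored` column records which values were
#' raised. Idempotent.
#'
#' @param obs A culture table.
#' @param floor Detection floor in cells/ml (default `4.57e5`).
#' @return The table with `density` floored and a `floored` flag.
#' @examples
#' obs <- data.frame(focal = "A", partner = NA, env = "Glucose",
#'                   replicate = 1, density = 3.1e5)
#' apply_detection_floor(obs)$density
#' @export
apply_detection_floor <- function(obs, floor = 4.57e5) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  newly <- obs$density < floor
  obs$floored <- if (is.null(obs$floored)) newly else (obs$floored | newly)
  obs$density <- pmax(obs$density, floor)
  obs
}

#' Summarise replicate yields per culture
#'
#' Per (focal, partner, env) culture: the arithmetic mean density, and
#' the mean and unbiased variance of the log10 densities. Observations
#' should already be floored so that all densities are positive.
#'
#' @param obs A floored culture table.
#' @return A data frame with one row per culture: `focal`, `partner`,
#'   `env`, `n_reps`, `mean_density`, `mean_log10`, `var_log10`
#'   (`NA` when only one replicate).
#' @export
summarize_yields <- function(obs) {
  if (nrow(obs) == 0L) stop("no observations to summarise")
  if (any(obs$density <= 0)) stop("non-positive density: floor the data first")
  key <- paste(obs$focal, ifelse(is.na(obs$partner), "", obs$partner),
               obs$env, sep = "\r")
  idx <- split(seq_len(nrow(obs)), key)
  rows <- lapply(idx, function(i) {
    d <- obs$density[i]
    l <- log10(d)
    data.frame(
      focal = obs$focal[i[1L]],
      partner = obs$partner[i[1L]],
      env = obs$env[i[1L]],
      n_reps = length(i),
      mean_density = mean(d),
      mean_log10 = mean(l),
      var_log10 = if (length(i) >= 2L) stats::var(l) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$env, out$focal, ifelse(is.na(out$partner), "", out$partner)), ,
      drop = FALSE]
}

# mono-culture mean densities as a lookup: species x env
mono_means <- function(yields) {
  m <- yields[is.na(yields$partner), c("focal", "env", "mean_density",
                                       "mean_log10", "var_log10")]
  rownames(m) <- NULL
  m
}

lookup_mono <- function(mono, species, env, what = "mean_density") {
  i <- match(paste(species, env, sep = "\r"),
             paste(mono$focal, mono$env, sep = "\r"))
  mono[[what]][i]
}
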