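#' The sixteen carbon sources and their biochemical categories
#'
#' The carbon compounds used in the co-culture assay, with the
#' biochemical category of each: sugars (mono-, di- and trisaccharides),
#' sugar alcohols, carboxylate ions, amino acids, and nucleic acids.
#' The category partition drives the pairwise PERMANOVA comparisons.
#'
#' @return A data frame with columns `source` and `category`.
#' @examples
#' table(carbon_sources()$category)
#' @export
carbon_sources <- function() {
  data.frame(
    source = c("Glucose", "Ribose", "Cellobiose", "Raffinose",
               "Glycerol", "Mannitol", "Sorbitol",
               "Acetate", "Citrate", "Succinate",
               "Alanine", "Glutamine", "Isoleucine", "Proline", "Serine",
               "Uridine"),
    category = c(rep("sugars", 4L),
                 rep("sugar alcohols", 3L),
                 rep("carboxylate ions", 3L),
                 rep("amino acids", 5L),
                 "nucleic acids"),
    stringsAsFactors = FALSE
  )
}

#' Construct an environment table
#'
#' An environment is a growth medium defined by the set of carbon
#' sources it contains and the total carbon concentration; when several
#' sources are mixed they contribute equal mass, so the per-source
#' concentration is `total / n_sources`. Zero sources encodes the
#' no-carbon control.
#'
#' @param env_id Character vector of environment identifiers.
#' @param sources List of character vectors, one per environment: the
#'   carbon sources present (may be empty).
#' @param total_mg_per_ml Total carbon concentration (mg/ml), recycled;
#'   default 1.0.
#' @return A data frame of class `"environment_table"` with columns
#'   `env`, `carbon_sources` (semicolon-separated), `n_sources`,
#'   `total_mg_per_ml`.
#' @export
environment_table <- function(env_id, sources, total_mg_per_ml = 1.0) {
  stopifnot(is.character(env_id), is.list(sources),
            length(env_id) == length(sources))
  if (anyDuplicated(env_id)) stop("duplicate environment ids")
  stopifnot(all(total_mg_per_ml > 0))
  n <- vapply(sources, function(s) length(unique(s)), integer(1))
  if (any(vapply(sources, anyDuplicated, integer(1)) > 0)) {
    stop("duplicate carbon source within an environment")
  }
  out <- data.frame(
    env = env_id,
    carbon_sources = vapply(sources, paste, character(1), collapse = ";"),
    n_sources = n,
    total_mg_per_ml = rep_len(total_mg_per_ml, length(env_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("environment_table", "data.frame")
  out
}

#' Split the semicolon-separated source field of an environment table
#'
#' @param envs An environment table.
#' @return A named list of character vectors (one per environment).
#' @export
environment_sources <- function(envs) {
  out <- strsplit(envs$carbon_sources, ";", fixed = TRUE)
  out <- lapply(out, function(s) s[nzchar(s)])
  names(out) <- envs$env
  out
}

#' Per-source concentration of each environment
#'
#' Equal mass contributions: `total / n_sources`; `NA` for the no-carbon
#' control.
#'
#' @param envs An environment table.
#' @return Numeric vector (mg/ml), named by environment.
#' @export
per_source_concentration <- function(envs) {
  out <- ifelse(envs$n_sources > 0,
                envs$total_mg_per_ml / envs$n_sources, NA_real_)
  names(out) <- envs$env
  out
}

#' The 32-environment study design
#'
#' The default design emulated by the synthetic-data module: the 16
#' single-carbon-source environments (named after their source), one
#' no-carbon control, and mixtures of 2, 4, 8 and 16 sources built by
#' recursively pairing the single sources (8 + 4 + 2 + 1 mixtures), all
#' at a fixed total of 1.0 mg/ml with equal mass per source.
#'
#' @param total_mg_per_ml Total carbon concentration, default 1.0.
#' @return An `"environment_table"` with 32 rows.
#' @examples
#' table(default_environment_design()$n_sources)
#' @export
default_environment_design <- function(total_mg_per_ml = 1.0) {
  src <- carbon_sources()$source
  ids <- c("none", src)
  sets <- c(list(character(0)), as.list(src))
  for (n in c(2L, 4L, 8L, 16L)) {
    k <- 16L / n
    for (b in seq_len(k)) {
      members <- src[((b - 1L) * n + 1L):(b * n)]
      ids <- c(ids, sprintf("mix%02d_%s", n, letters[b]))
      sets <- c(sets, list(members))
    }
  }
  environment_table(ids, sets, total_mg_per_ml)
}

#' Read / write an environment table
#'
#' CSV with header `env,carbon_sources,total_mg_per_ml`; the
#' `carbon_sources` field is semicolon-separated and empty for the
#' no-carbon control. `n_sources` is recomputed on read.
#'
#' @param path File path.
#' @return `read_environment_table()` returns an `"environment_table"`.
#' @export
read_environment_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("env", "carbon_sources", "total_mg_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sets <- lapply(strsplit(df$carbon_sources, ";", fixed = TRUE),
                 function(s) s[nzchar(s)])
  environment_table(df$env, sets, as.numeric(df$total_mg_per_ml))
}

#' @param envs An environment table to write.
#' @rdname read_environment_table
#' @export
write_environment_table <- function(envs, path) {
  utils::write.csv(
    envs[, c("env", "carbon_sources", "total_mg_per_ml")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
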