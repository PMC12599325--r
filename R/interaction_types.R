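#' Log2 effect size of co-culture on yield
#'
#' `E = log2(mean_co / mean_mono)`: the unidirectional effect of a
#' partner on the focal species, as the log2 ratio of the focal
#' species' mean co-culture density to its mean mono-culture density.
#' Flooring guarantees positive means, hence finite E.
#'
#' @param mean_co,mean_mono Mean densities (cells/ml), vectorised.
#' @return Numeric vector of log2 ratios.
#' @examples
#' compute_E(8e6, 2e6) # 2
#' @export
compute_E <- function(mean_co, mean_mono) {
  if (any(!is.finite(mean_co)) || any(!is.finite(mean_mono)) ||
      any(mean_co <= 0) || any(mean_mono <= 0)) {
    stop("means must be positive and finite (floor the data first)")
  }
  log2(mean_co / mean_mono)
}

#' Interaction-type angle theta
#'
#' The angle (degrees, in \[-90, 90\]) between the point
#' `(min(E_ij, E_ji), max(E_ij, E_ji))` and the anti-diagonal
#' `max = -min`:
#' `theta = arctan((E_ij + E_ji) / |E_ij - E_ji|) * 180 / pi` when the
#' two effects differ, and 0 when both are zero. Positive angles are
#' net-synergistic, negative net-competitive; -90 means mutual equal
#' inhibition, +90 mutual equal facilitation.
#'
#' Two conventions complete the definition: when all four underlying
#' mean densities sit at the detection floor (`at_floor`), theta is 0;
#' and when the two effects are exactly equal but nonzero (denominator
#' zero) theta is the continuity limit `sign(E_ij + E_ji) * 90`.
#'
#' @param E_ij,E_ji Log2 effect sizes (vectorised).
#' @param at_floor Logical, recycled: all four means at the floor.
#' @return Numeric vector of angles in degrees.
#' @examples
#' compute_theta(2, 1)  # 71.565
#' compute_theta(1, -1) # 0
#' @export
compute_theta <- function(E_ij, E_ji, at_floor = FALSE) {
  stopifnot(all(is.finite(E_ij)), all(is.finite(E_ji)))
  at_floor <- rep_len(at_floor, length(E_ij))
  s <- E_ij + E_ji
  d <- abs(E_ij - E_ji)
  theta <- ifelse(d > 0, atan2(s, d) * 180 / pi,
                  ifelse(s == 0, 0, sign(s) * 90))
  ifelse(at_floor, 0, theta)
}

#' Effect pairs and interaction angles for a whole dataset
#'
#' For every unordered pair and environment: the two log2 effects, the
#' plotting coordinates `(min, max)`, the angle theta, and flags for
#' the all-at-floor rule and the equal-effects continuity extension.
#'
#' @param obs A floored culture table.
#' @param floor Detection floor used to flag records whose four means
#'   all sit at the floor (default `4.57e5`).
#' @return Data frame: `species_i`, `species_j`, `env`, `E_ij`, `E_ji`,
#'   `coord_min`, `coord_max`, `theta`, `at_floor`, `equal_effects`.
#'   `E_ij` is the effect on `species_i` (names sorted within pair).
#' @export
interaction_types <- function(obs, floor = 4.57e5) {
  yields <- summarize_yields(obs)
  mono <- mono_means(yields)
  co <- yields[!is.na(yields$partner), , drop = FALSE]
  if (nrow(co) == 0L) stop("no co-culture observations")
  si <- pmin(co$focal, co$partner)
  sj <- pmax(co$focal, co$partner)
  pk <- paste(si, sj, co$env, sep = "\r")
  rows <- lapply(split(seq_len(nrow(co)), pk), function(i) {
    if (length(i) != 2L) {
      stop("each pair-environment needs both co-culture directions")
    }
    a <- i[order(co$focal[i])][1L]
    b <- setdiff(i, a)
    env <- co$env[a]
    mi <- lookup_mono(mono, co$focal[a], env)
    mj <- lookup_mono(mono, co$focal[b], env)
    if (is.na(mi) || is.na(mj)) {
      stop(sprintf("missing mono-culture in env '%s'", env))
    }
    E_ij <- compute_E(co$mean_density[a], mi)
    E_ji <- compute_E(co$mean_density[b], mj)
    at_fl <- all(abs(c(co$mean_density[a], co$mean_density[b], mi, mj) -
                       floor) <= 1e-9 * floor)
    data.frame(
      species_i = co$focal[a], species_j = co$focal[b], env = env,
      E_ij = E_ij, E_ji = E_ji,
      coord_min = min(E_ij, E_ji), coord_max = max(E_ij, E_ji),
      theta = compute_theta(E_ij, E_ji, at_fl),
      at_floor = at_fl,
      equal_effects = (E_ij == E_ji) && (E_ij != 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$env, out$species_i, out$species_j), , drop = FALSE]
}

#' Average interaction angle per environment or per pair
#'
#' `by = "environment"`: mean theta over all pairs observed in each
#' environment. `by = "pair"`: mean theta for each pair over the
#' single-carbon-source environments only (pass those ids via
#' `single_envs`), matching how the per-pair average is defined.
#'
#' @param types Output of [interaction_types()].
#' @param by `"environment"` or `"pair"`.
#' @param single_envs Character vector of single-source environment ids
#'   (required for `by = "pair"`).
#' @return Data frame with the grouping columns, `n`, and `theta_bar`.
#' @export
average_theta <- function(types, by = c("environment", "pair"),
                          single_envs = NULL) {
  by <- match.arg(by)
  if (nrow(types) == 0L) stop("empty interaction-type table")
  if (by == "environment") {
    agg <- stats::aggregate(types$theta, by = list(env = types$env),
                            FUN = mean)
    n <- stats::aggregate(types$theta, by = list(env = types$env),
                          FUN = length)
    data.frame(env = agg$env, n = n$x, theta_bar = agg$x,
               stringsAsFactors = FALSE)
  } else {
    if (is.null(single_envs)) {
      stop("single_envs is required for per-pair averages")
    }
    sub <- types[types$env %in% single_envs, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no records in the given single_envs")
    g <- list(species_i = sub$species_i, species_j = sub$species_j)
    agg <- stats::aggregate(sub$theta, by = g, FUN = mean)
    n <- stats::aggregate(sub$theta, by = g, FUN = length)
    data.frame(species_i = agg$species_i, species_j = agg$species_j,
               n = n$x, theta_bar = agg$x, stringsAsFactors = FALSE)
  }
}
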