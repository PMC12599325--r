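#' Configuration for a planted-effect dataset
#'
#' Describes a ground-truth dataset for exercising the inference
#' chain: per (species, environment) true mono-culture mean densities,
#' per (pair, environment) true log2 effects, and multiplicative
#' (log10-normal) replicate noise. With zero noise the generated
#' tables are deterministic and the inferred effects reproduce the
#' planted ones exactly.
#'
#' @param effects Data frame with columns `species_i`, `species_j`,
#'   `env`, `E_true_ij`, `E_true_ji` (log2 units; `E_true_ij` is the
#'   effect on `species_i`).
#' @param mono_means Data frame with columns `species`, `env`,
#'   `mono_mean` (cells/ml, > 0) covering every species referenced by
#'   `effects`.
#' @param noise_sd_log10 Replicate noise standard deviation on log10
#'   density (>= 0).
#' @param n_reps Replicates per culture (default 3).
#' @param seed Integer seed.
#' @param detection_floor Floor applied to generated densities.
#' @return An object of class `"planted_config"`.
#' @export
planted_config <- function(effects, mono_means, noise_sd_log10 = 0.05,
                           n_reps = 3L, seed = 1L,
                           detection_floor = 4.57e5) {
  stopifnot(all(c("species_i", "species_j", "env",
                  "E_true_ij", "E_true_ji") %in% names(effects)))
  stopifnot(all(c("species", "env", "mono_mean") %in% names(mono_means)))
  if (any(mono_means$mono_mean <= 0)) {
    stop("config error: non-positive mono-culture mean")
  }
  stopifnot(noise_sd_log10 >= 0, n_reps >= 1)
  need <- unique(rbind(
    data.frame(species = effects$species_i, env = effects$env),
    data.frame(species = effects$species_j, env = effects$env)))
  have <- paste(mono_means$species, mono_means$env)
  miss <- !(paste(need$species, need$env) %in% have)
  if (any(miss)) stop("mono_means does not cover all (species, env)")
  structure(list(effects = effects, mono_means = mono_means,
                 noise_sd_log10 = noise_sd_log10,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 detection_floor = detection_floor),
            class = "planted_config")
}

#' Default planted design
#'
#' 100 pair-environment records over 8 species (28 pairs) and 4
#' environments, with true effect magnitudes drawn uniformly from
#' `effect_magnitudes` and random signs, and mono-culture means drawn
#' log-uniformly between `10^6.5` and `10^8` cells/ml.
#'
#' @param n_records Number of (pair, environment) records (default 100).
#' @param effect_magnitudes Candidate |E_true| values (default
#'   `c(0, 1, 1.5)`).
#' @param noise_sd_log10,n_reps,seed,detection_floor As in
#'   [planted_config()].
#' @return A `"planted_config"`.
#' @export
default_planted_config <- function(n_records = 100L,
                                   effect_magnitudes = c(0, 1, 1.5),
                                   noise_sd_log10 = 0.05, n_reps = 3L,
                                   seed = 1L, detection_floor = 4.57e5) {
  species <- sprintf("sp%d", 1:8)
  pairs <- utils::combn(species, 2L)
  n_envs <- ceiling(n_records / ncol(pairs))
  envs <- sprintf("e%02d", seq_len(n_envs))
  grid <- expand.grid(pair = seq_len(ncol(pairs)), env = envs,
                      stringsAsFactors = FALSE)[seq_len(n_records), ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "planted-design"))
  draw <- function(n) {
    mag <- sample(effect_magnitudes, n, replace = TRUE)
    mag * sample(c(-1, 1), n, replace = TRUE)
  }
  effects <- data.frame(
    species_i = pairs[1L, grid$pair], species_j = pairs[2L, grid$pair],
    env = grid$env,
    E_true_ij = draw(n_records), E_true_ji = draw(n_records),
    stringsAsFactors = FALSE)
  mm <- expand.grid(species = species, env = envs,
                    stringsAsFactors = FALSE)
  mm$mono_mean <- 10^stats::runif(nrow(mm), 6.5, 8)
  planted_config(effects, mm, noise_sd_log10, n_reps, seed,
                 detection_floor)
}

#' Generate a planted-effect dataset
#'
#' Mono-culture replicates are `10^(log10(mono_mean) + noise)`;
#' co-culture replicates of the focal species are
#' `10^(log10(mono_mean * 2^E_true) + noise)`, noise being Gaussian on
#' log10 with the configured standard deviation. All densities are
#' floored. The truth table records the planted effects and the
#' interaction class they imply (the sign of each effect, zero meaning
#' unaffected).
#'
#' @param config A `"planted_config"`.
#' @return List with `culture` (a floored culture table) and `truth`
#'   (the effects with `call_ij_true`, `call_ji_true`, `class_true`).
#' @export
generate_planted_dataset <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "planted-tables"))
  nr <- config$n_reps
  sd <- config$noise_sd_log10
  noisy <- function(mean_density, n) {
    10^(log10(mean_density) + stats::rnorm(n, 0, sd))
  }
  mm <- config$mono_means
  mono <- do.call(rbind, lapply(seq_len(nrow(mm)), function(i) {
    data.frame(focal = mm$species[i], partner = NA_character_,
               env = mm$env[i], replicate = seq_len(nr),
               density = noisy(mm$mono_mean[i], nr),
               stringsAsFactors = FALSE)
  }))
  ef <- config$effects
  mono_of <- function(sp, env) {
    mm$mono_mean[match(paste(sp, env), paste(mm$species, mm$env))]
  }
  co <- do.call(rbind, lapply(seq_len(nrow(ef)), function(i) {
    mi <- mono_of(ef$species_i[i], ef$env[i])
    mj <- mono_of(ef$species_j[i], ef$env[i])
    rbind(
      data.frame(focal = ef$species_i[i], partner = ef$species_j[i],
                 env = ef$env[i], replicate = seq_len(nr),
                 density = noisy(mi * 2^ef$E_true_ij[i], nr),
                 stringsAsFactors = FALSE),
      data.frame(focal = ef$species_j[i], partner = ef$species_i[i],
                 env = ef$env[i], replicate = seq_len(nr),
                 density = noisy(mj * 2^ef$E_true_ji[i], nr),
                 stringsAsFactors = FALSE))
  }))
  culture <- apply_detection_floor(rbind(mono, co),
                                   config$detection_floor)
  sign_call <- function(e) c("-", "0", "+")[sign(e) + 2]
  truth <- ef
  truth$call_ij_true <- sign_call(ef$E_true_ij)
  truth$call_ji_true <- sign_call(ef$E_true_ji)
  truth$class_true <- classify_pair(truth$call_ij_true,
                                    truth$call_ji_true)
  list(culture = culture, truth = truth)
}

#' Configuration of the batch consumer-resource simulator
#'
#' A resource-explicit batch culture: species consume finite resource
#' pools (the supplied carbon sources plus optional by-product pools),
#' convert a fraction `1 - beta` of consumed carbon to biomass at yield
#' `gamma`, and secrete the remaining fraction `beta` into their
#' designated by-product pool, which other species may consume.
#' Discrete-time update with demand-proportional sharing when a
#' resource would be over-consumed within a step.
#'
#' @param species Character vector of species names.
#' @param resources Character vector of resource names; the first
#'   `n_primary` are the suppliable carbon sources, the rest are
#'   by-product pools (initially empty).
#' @param n_primary Number of suppliable sources.
#' @param uptake Species x resources matrix of uptake rate constants
#'   (mg per cell per hour, >= 0).
#' @param yield Biomass yield (cells per mg of carbon routed to
#'   biomass); scalar or species x resources matrix. Default `1e9`.
#' @param byproduct_fraction Fraction of consumed carbon re-secreted
#'   (in `[0, 1)`); scalar or species x resources matrix. Default 0.
#' @param secretion_target Character vector per species: the by-product
#'   resource receiving its secreted carbon (`NA` = nothing secreted).
#' @param inoculum_mono,inoculum_co Starting densities (cells/ml):
#'   `1e5` for mono-cultures and `5e4` per species for co-cultures
#'   (equal-volume mixing of equally dense inocula).
#' @param hours Culture duration (default 72).
#' @param dt Time step in hours (default 0.05).
#' @param noise_sd_log10 Replicate measurement noise on log10 density
#'   (default 0).
#' @param n_reps Replicates per culture (default 3).
#' @param seed Integer seed (used only for replicate noise).
#' @param detection_floor Floor applied to generated densities.
#' @return An object of class `"resource_config"`.
#' @export
resource_model_config <- function(species, resources, n_primary,
                                  uptake, yield = 1e9,
                                  byproduct_fraction = 0,
                                  secretion_target = NULL,
                                  inoculum_mono = 1e5,
                                  inoculum_co = 5e4,
                                  hours = 72, dt = 0.05,
                                  noise_sd_log10 = 0, n_reps = 3L,
                                  seed = 1L, detection_floor = 4.57e5) {
  ns <- length(species); nr <- length(resources)
  stopifnot(is.matrix(uptake), nrow(uptake) == ns, ncol(uptake) == nr)
  if (any(uptake < 0)) stop("config error: negative uptake")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- matrix(x, ns, nr)
    stopifnot(is.matrix(x), nrow(x) == ns, ncol(x) == nr)
    x
  }
  yield <- expand(yield)
  beta <- expand(byproduct_fraction)
  if (any(yield < 0)) stop("config error: negative yield")
  if (any(beta < 0 | beta >= 1)) {
    stop("config error: byproduct fraction outside [0, 1)")
  }
  if (is.null(secretion_target)) {
    secretion_target <- rep(NA_character_, ns)
  }
  stopifnot(length(secretion_target) == ns)
  tgt <- secretion_target[!is.na(secretion_target)]
  if (length(tgt) && !all(tgt %in% resources[-seq_len(n_primary)])) {
    stop("secretion targets must be non-primary resource pools")
  }
  stopifnot(inoculum_mono > 0, inoculum_co > 0, hours > 0, dt > 0,
            n_primary >= 1, n_primary <= nr)
  dimnames(uptake) <- dimnames(yield) <- dimnames(beta) <-
    list(species, resources)
  structure(list(species = species, resources = resources,
                 n_primary = as.integer(n_primary), uptake = uptake,
                 yield = yield, beta = beta,
                 secretion_target = secretion_target,
                 inoculum_mono = inoculum_mono, inoculum_co = inoculum_co,
                 hours = hours, dt = dt,
                 noise_sd_log10 = noise_sd_log10,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 detection_floor = detection_floor),
            class = "resource_config")
}

#' Default 8-species resource community
#'
#' The community emulating the study design: eight species over the
#' sixteen named carbon sources. Four staple sources (Glucose,
#' Glycerol, Succinate, Proline) are usable by every species at
#' species-specific rates; eight sources are private to one species
#' each; the remaining four are shared by two species each. Every
#' species secretes a quarter of the carbon it consumes from primary
#' sources into its own by-product pool, which the cyclically next
#' species can consume, so cross-feeding (commensalism) is possible in
#' sparse environments while shared sources generate resource
#' competition that intensifies with the number of sources mixed.
#'
#' @param noise_sd_log10 Replicate noise (default 0.05).
#' @param seed Integer seed (default 1).
#' @return A `"resource_config"`.
#' @export
default_resource_config <- function(noise_sd_log10 = 0.05, seed = 1L) {
  species <- sprintf("sp%d", 1:8)
  src <- carbon_sources()$source
  byp <- sprintf("byp%d", 1:8)
  u0 <- 5e-10
  u <- matrix(0, 8, 24, dimnames = list(species, c(src, byp)))
  staples <- c("Glucose", "Glycerol", "Succinate", "Proline")
  w <- c(0.7, 1.0, 0.4, 0.85, 0.55, 0.95, 0.45, 0.8)
  for (s in 1:8) u[s, staples] <- u0 * w[s]
  private <- c("Ribose", "Cellobiose", "Mannitol", "Sorbitol",
               "Acetate", "Alanine", "Glutamine", "Serine")
  for (s in 1:8) u[s, private[s]] <- 1.2 * u0
  shared <- list(Raffinose = c(1, 5), Citrate = c(2, 6),
                 Isoleucine = c(3, 7), Uridine = c(4, 8))
  for (nm in names(shared)) u[shared[[nm]], nm] <- 0.8 * u0
  for (s in 1:8) u[(s %% 8) + 1, byp[s]] <- 0.8 * u0
  beta <- matrix(0, 8, 24, dimnames = dimnames(u))
  beta[, src] <- 0.25
  resource_model_config(
    species = species, resources = c(src, byp), n_primary = 16L,
    uptake = u, yield = 1e9, byproduct_fraction = beta,
    secretion_target = byp, noise_sd_log10 = noise_sd_log10,
    seed = seed)
}

#' Simulate one batch culture
#'
#' Deterministic discrete-time dynamics for a one- or two-species
#' community in one environment: per step, each species demands
#' `uptake * density * dt` of every resource; when total demand
#' exceeds what remains, consumption is shared pro rata to demand;
#' biomass increases by `yield * (1 - beta) * consumed` and
#' `beta * consumed` flows into the consumer's by-product pool.
#' Resources never go negative and densities never decrease. Carbon
#' mass balance (consumed = biomass carbon + secreted) holds to
#' machine precision by construction and is reported for checking.
#'
#' @param config A `"resource_config"`.
#' @param env One row of an environment table (or an id into `envs`).
#' @param community Character vector of 1 or 2 species names.
#' @param inoculum Optional starting densities (defaults to the
#'   configured mono/co inocula).
#' @param envs Environment table used when `env` is an id.
#' @return List with `final` (named densities), `resources` (remaining
#'   pools), `consumed`, `biomass_carbon`, `secreted` (cumulative
#'   mg/ml), and `steps`.
#' @export
resource_batch_dynamics <- function(config, env, community,
                                    inoculum = NULL, envs = NULL) {
  stopifnot(inherits(config, "resource_config"))
  if (is.character(env) && length(env) == 1L) {
    if (is.null(envs)) stop("envs table required when env is an id")
    env <- envs[envs$env == env, , drop = FALSE]
    if (nrow(env) != 1L) stop("unknown environment id")
  }
  stopifnot(length(community) %in% c(1L, 2L),
            all(community %in% config$species))
  srcs <- strsplit(env$carbon_sources, ";", fixed = TRUE)[[1]]
  srcs <- srcs[nzchar(srcs)]
  bad <- setdiff(srcs, config$resources[seq_len(config$n_primary)])
  if (length(bad)) {
    stop("environment sources not in the model: ",
         paste(bad, collapse = ", "))
  }
  R <- stats::setNames(numeric(length(config$resources)),
                       config$resources)
  if (length(srcs)) R[srcs] <- env$total_mg_per_ml / length(srcs)
  if (is.null(inoculum)) {
    inoculum <- rep(if (length(community) == 1L) config$inoculum_mono
                    else config$inoculum_co, length(community))
  }
  X <- stats::setNames(inoculum, community)
  u <- config$uptake[community, , drop = FALSE]
  g <- config$yield[community, , drop = FALSE]
  b <- config$beta[community, , drop = FALSE]
  tgt <- config$secretion_target[match(community, config$species)]
  usable <- colSums(u) > 0
  can_secrete <- !is.na(tgt)
  n_steps <- ceiling(config$hours / config$dt)
  consumed_total <- 0; biomass_carbon <- 0; secreted_total <- 0
  dt <- config$dt
  for (step in seq_len(n_steps)) {
    avail <- R[usable]
    if (all(avail < 1e-15)) break
    demand <- u * (X * dt) # rows species, cols resources
    dem_k <- colSums(demand)
    take <- pmin(R, dem_k)
    frac <- ifelse(dem_k > 0, take / dem_k, 0)
    cons <- sweep(demand, 2L, frac, `*`)
    grow <- rowSums(g * (1 - b) * cons)
    sec <- rowSums(b * cons)
    X <- X + grow
    R <- R - take
    for (s in seq_along(community)) {
      if (can_secrete[s] && sec[s] > 0) R[tgt[s]] <- R[tgt[s]] + sec[s]
    }
    consumed_total <- consumed_total + sum(cons)
    biomass_carbon <- biomass_carbon + sum((1 - b) * cons)
    secreted_total <- secreted_total + sum(sec)
  }
  list(final = X, resources = R, consumed = consumed_total,
       biomass_carbon = biomass_carbon, secreted = secreted_total,
       steps = step)
}

#' Generate a full mono- plus co-culture dataset from the simulator
#'
#' Runs every mono-culture (each species) and every co-culture (each
#' unordered pair) in every environment, turns each deterministic
#' endpoint into replicates with multiplicative log10-normal noise,
#' and floors the result.
#'
#' @param config A `"resource_config"`.
#' @param envs An environment table (default the 32-environment
#'   design).
#' @return A floored culture table.
#' @export
generate_resource_dataset <- function(config,
                                      envs = default_environment_design()) {
  stopifnot(inherits(config, "resource_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "resource-dataset"))
  nr <- config$n_reps
  sd <- config$noise_sd_log10
  pairs <- if (length(config$species) >= 2L) {
    utils::combn(config$species, 2L)
  } else NULL
  rows <- vector("list", nrow(envs) *
                   (length(config$species) + NCOL(pairs)))
  k <- 0L
  for (e in seq_len(nrow(envs))) {
    env <- envs[e, , drop = FALSE]
    for (sp in config$species) {
      fin <- resource_batch_dynamics(config, env, sp)$final
      k <- k + 1L
      rows[[k]] <- data.frame(
        focal = sp, partner = NA_character_, env = env$env,
        replicate = seq_len(nr),
        density = 10^(log10(fin) + stats::rnorm(nr, 0, sd)),
        stringsAsFactors = FALSE)
    }
    if (!is.null(pairs)) {
      for (pc in seq_len(ncol(pairs))) {
        pr <- pairs[, pc]
        fin <- resource_batch_dynamics(config, env, pr)$final
        k <- k + 1L
        rows[[k]] <- data.frame(
          focal = pr, partner = rev(pr), env = env$env,
          replicate = rep(seq_len(nr), each = 2L),
          density = 10^(log10(rep(fin, nr)) +
                          stats::rnorm(2L * nr, 0, sd)),
          stringsAsFactors = FALSE)
      }
    }
  }
  apply_detection_floor(do.call(rbind, rows), config$detection_floor)
}
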