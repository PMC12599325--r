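# Small in-code fixtures shared across the suite.

# A culture table from vectors; partner = NA marks mono-cultures.
make_obs <- function(focal, partner, env, replicate, density) {
  data.frame(focal = focal, partner = partner, env = env,
             replicate = replicate, density = density,
             stringsAsFactors = FALSE)
}

# Mono + co triplicates for one pair in one environment, from the
# exact replicate densities given.
pair_env_obs <- function(env, sp_i, sp_j, mono_i, mono_j, co_i, co_j) {
  rbind(
    make_obs(sp_i, NA_character_, env, 1:3, mono_i),
    make_obs(sp_j, NA_character_, env, 1:3, mono_j),
    make_obs(sp_i, sp_j, env, 1:3, co_i),
    make_obs(sp_j, sp_i, env, 1:3, co_j))
}

# Noise-free planted configuration on a small grid.
small_planted_config <- function(noise = 0, seed = 1,
                                 effects = NULL) {
  if (is.null(effects)) {
    effects <- data.frame(
      species_i = c("A", "A", "B"), species_j = c("B", "C", "C"),
      env = "e1",
      E_true_ij = c(1, 0, -1), E_true_ji = c(-1, 0.5, -1),
      stringsAsFactors = FALSE)
  }
  sp <- unique(c(effects$species_i, effects$species_j))
  mm <- expand.grid(species = sp, env = unique(effects$env),
                    stringsAsFactors = FALSE)
  mm$mono_mean <- 2e7
  planted_config(effects, mm, noise_sd_log10 = noise, seed = seed)
}

# total within-cluster sum of squares of a labelled 1-D split
wss2 <- function(x, lab) {
  s <- 0
  for (g in unique(lab)) {
    xs <- x[lab == g]
    if (length(xs) > 1) s <- s + sum((xs - mean(xs))^2)
  }
  s
}

# global-optimum two-partition WSS by brute force over all 2^(n-1)-1
# non-trivial assignments (independent of any sorting argument)
brute_force_best_wss <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(0, as.integer(intToBits(code)[1:(n - 1)]))
    if (length(unique(lab)) < 2) next
    best <- min(best, wss2(x, lab))
  }
  best
}
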