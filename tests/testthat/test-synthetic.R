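test_that("noise-free planting is recovered exactly by the effect size", {
  cfg <- small_planted_config(noise = 0)
  ds <- generate_planted_dataset(cfg)
  tt <- interaction_types(ds$culture)
  key <- paste(tt$species_i, tt$species_j, tt$env)
  tk <- paste(ds$truth$species_i, ds$truth$species_j, ds$truth$env)
  m <- match(tk, key)
  expect_equal(tt$E_ij[m], ds$truth$E_true_ij, tolerance = 1e-12)
  expect_equal(tt$E_ji[m], ds$truth$E_true_ji, tolerance = 1e-12)
})

test_that("null planting makes co-culture equal mono-culture", {
  effects <- data.frame(species_i = "A", species_j = "B", env = "e1",
                        E_true_ij = 0, E_true_ji = 0)
  ds <- generate_planted_dataset(small_planted_config(0, effects = effects))
  cu <- ds$culture
  mono_a <- cu$density[cu$focal == "A" & is.na(cu$partner)]
  co_a <- cu$density[cu$focal == "A" & !is.na(cu$partner)]
  expect_equal(sort(mono_a), sort(co_a))
  expect_equal(ds$truth$class_true, "neutralism")
})

test_that("planted generation rejects bad configs and is seed-stable", {
  effects <- data.frame(species_i = "A", species_j = "B", env = "e1",
                        E_true_ij = 1, E_true_ji = 0)
  mm <- data.frame(species = c("A", "B"), env = "e1",
                   mono_mean = c(1e7, -2))
  expect_error(planted_config(effects, mm), "non-positive")
  mm2 <- data.frame(species = "A", env = "e1", mono_mean = 1e7)
  expect_error(planted_config(effects, mm2), "cover")

  d1 <- generate_planted_dataset(default_planted_config(seed = 5))
  d2 <- generate_planted_dataset(default_planted_config(seed = 5))
  expect_identical(d1, d2)
  expect_equal(nrow(d1$truth), 100L)
})

test_that("batch dynamics respect mass balance and simple closed forms", {
  sp <- "s1"
  cfg <- resource_model_config(
    species = sp, resources = "r1", n_primary = 1,
    uptake = matrix(5e-10, 1, 1), yield = 1e9,
    inoculum_mono = 1e5, hours = 72, dt = 0.05)
  envs <- environment_table(c("none", "full"),
                            list(character(0), "r1"))
  # nothing to consume: density stays at the inoculum
  none <- resource_batch_dynamics(cfg, "none", sp, envs = envs)
  expect_equal(unname(none$final), 1e5)
  # full consumption, no secretion: X = X0 + yield * 1.0 mg/ml
  full <- resource_batch_dynamics(cfg, "full", sp, envs = envs)
  expect_equal(unname(full$final), 1e5 + 1e9, tolerance = 1e-6)
  expect_equal(full$consumed, 1.0, tolerance = 1e-9)
  # mass balance: consumed = biomass carbon + secreted
  expect_equal(full$consumed, full$biomass_carbon + full$secreted,
               tolerance = 1e-9 * max(full$consumed, 1))
})

test_that("identical competitors split a single resource exactly in half", {
  cfg <- resource_model_config(
    species = c("s1", "s2"), resources = "r1", n_primary = 1,
    uptake = matrix(5e-10, 2, 1), yield = 1e9,
    inoculum_mono = 1e5, inoculum_co = 5e4)
  envs <- environment_table("full", list("r1"))
  co <- resource_batch_dynamics(cfg, "full", c("s1", "s2"), envs = envs)
  expect_equal(unname(co$final[1]), unname(co$final[2]), tolerance = 1e-12)
  # each gains half of the total resource yield
  expect_equal(unname(co$final[1]), 5e4 + 1e9 / 2, tolerance = 1e-3)
  # the implied effect is negative for both: resource competition
  mono <- resource_batch_dynamics(cfg, "full", "s1", envs = envs)
  E <- log2(co$final[1] / mono$final)
  expect_lt(E, 0)
  expect_equal(unname(E), log2((5e4 + 5e8) / (1e5 + 1e9)),
               tolerance = 1e-6)
})

test_that("cross-feeding via by-product pools facilitates the consumer", {
  # s1 eats r1 and secretes half into pool b1; s2 can only eat b1
  cfg <- resource_model_config(
    species = c("s1", "s2"), resources = c("r1", "b1"), n_primary = 1,
    uptake = rbind(c(5e-10, 0), c(0, 5e-10)),
    yield = 1e9,
    byproduct_fraction = rbind(c(0.5, 0), c(0, 0)),
    secretion_target = c("b1", NA))
  envs <- environment_table("full", list("r1"))
  co <- resource_batch_dynamics(cfg, "full", c("s1", "s2"), envs = envs)
  mono2 <- resource_batch_dynamics(cfg, "full", "s2", envs = envs)
  expect_equal(unname(mono2$final), 1e5) # cannot grow alone
  expect_gt(unname(co$final["s2"]), 10 * 5e4) # fed by s1's secretion
  expect_equal(co$consumed, co$biomass_carbon + co$secreted,
               tolerance = 1e-9)
})

test_that("the generated dataset is floored, complete and seed-stable", {
  cfg <- default_resource_config(noise_sd_log10 = 0.03, seed = 9)
  envs <- default_environment_design()[c(1, 2, 18), ] # none, single, mix
  d1 <- generate_resource_dataset(cfg, envs)
  d2 <- generate_resource_dataset(cfg, envs)
  expect_identical(d1, d2)
  expect_true(all(d1$density >= 4.57e5))
  # 8 mono + 28 co (x2 focals) per environment, 3 replicates each
  expect_equal(nrow(d1), 3 * (8 + 56) * 3)
  # no-carbon control: everything at the floor
  expect_true(all(d1$density[d1$env == "none"] == 4.57e5))
})

test_that("all-zero uptake leaves every culture at the floor", {
  cfg <- resource_model_config(
    species = c("s1", "s2"), resources = "r1", n_primary = 1,
    uptake = matrix(0, 2, 1), noise_sd_log10 = 0)
  envs <- environment_table("full", list("r1"))
  d <- generate_resource_dataset(cfg, envs)
  expect_true(all(d$density == 4.57e5))
})

test_that("config validation rejects inconsistent simulators", {
  expect_error(resource_model_config(
    species = "s1", resources = "r1", n_primary = 1,
    uptake = matrix(-1, 1, 1)), "negative uptake")
  expect_error(resource_model_config(
    species = "s1", resources = "r1", n_primary = 1,
    uptake = matrix(1e-10, 1, 1), byproduct_fraction = 1), "fraction")
  expect_error(resource_model_config(
    species = "s1", resources = "r1", n_primary = 1,
    uptake = matrix(1e-10, 1, 1), secretion_target = "r1"),
    "non-primary")
})
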