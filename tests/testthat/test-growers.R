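test_that("grower split separates clear clusters and honours the floor", {
  expect_equal(ward_growers(c(5.66, 5.70, 8.9, 9.0)),
               c("non_grower", "non_grower", "grower", "grower"))
  lf <- log10(4.57e5)
  expect_equal(ward_growers(rep(lf, 5)), rep("non_grower", 5))
  expect_error(ward_growers(8.2), "at least two")
  # the guard for near-merged clusters assigns a single label
  expect_equal(ward_growers(c(8.0, 8.1, 8.2, 8.3)), rep("grower", 4))
  expect_equal(ward_growers(lf + c(0.0, 0.1, 0.2, 0.3)),
               rep("non_grower", 4))
})

test_that("the two-cluster cut is the global optimum of Ward's criterion", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- runif(n, 5, 9)
    sp <- cocultr:::ward_split_1d(x)
    expect_equal(wss2(x, sp), brute_force_best_wss(x), tolerance = 1e-9)
  }
})

test_that("grower labels are monotone in the mean yield", {
  set.seed(9)
  for (i in 1:20) {
    x <- runif(sample(5:20, 1), 5.7, 9)
    lab <- ward_growers(x)
    if (length(unique(lab)) == 2) {
      expect_gt(min(x[lab == "grower"]), max(x[lab == "non_grower"]))
    }
  }
})

test_that("growth calls and grower fractions per carbon number", {
  envs <- environment_table(c("none", "s1", "m12"),
                            list(character(0), "src1",
                                 c("src1", "src2")))
  obs <- rbind(
    make_obs("A", NA_character_, "none", 1:3, rep(4.57e5, 3)),
    make_obs("A", NA_character_, "s1", 1:3, rep(5e8, 3)),
    make_obs("A", NA_character_, "m12", 1:3, rep(4e8, 3)),
    make_obs("B", NA_character_, "none", 1:3, rep(4.57e5, 3)),
    make_obs("B", NA_character_, "s1", 1:3, rep(4.6e5, 3)),
    make_obs("B", NA_character_, "m12", 1:3, rep(6e8, 3)))
  calls <- growth_calls(obs)
  expect_equal(calls$label[calls$species == "A" & calls$env == "s1"],
               "grower")
  expect_equal(calls$label[calls$species == "B" & calls$env == "s1"],
               "non_grower")
  fr <- grower_fraction_by_carbon_number(calls, envs)
  expect_equal(fr$frac_growers[fr$n_sources == 0], 0)
  expect_equal(fr$frac_growers[fr$n_sources == 1], 0.5)
  expect_equal(fr$frac_growers[fr$n_sources == 2], 1)
  # all growers everywhere
  allg <- data.frame(species = "A", env = c("none", "s1", "m12"),
                     mean_log10 = 9, label = "grower")
  fr2 <- grower_fraction_by_carbon_number(allg, envs)
  expect_true(all(fr2$frac_growers == 1))
})

test_that("stratification tallies by hand and conserves counts", {
  envs <- environment_table(c("s1", "s2"), list("src1", "src2"))
  set.seed(21)
  classes <- data.frame(
    species_i = rep(c("A", "A", "B"), 2),
    species_j = rep(c("B", "C", "C"), 2),
    env = rep(c("s1", "s2"), each = 3),
    class = c("competition", "neutralism", "commensalism",
              "competition", "competition", "mutualism"),
    stringsAsFactors = FALSE)
  calls <- expand.grid(species = c("A", "B", "C"), env = c("s1", "s2"),
                       stringsAsFactors = FALSE)
  calls$mean_log10 <- 8
  calls$label <- c("grower", "grower", "non_grower",
                   "grower", "grower", "grower")
  st <- stratify_interactions(classes, calls, envs)
  expect_equal(st$records$stratum,
               c("both_growers", "any_non_grower", "any_non_grower",
                 "both_growers", "both_growers", "both_growers"))
  # counts conserve the full class table
  expect_equal(sum(st$counts$count), nrow(classes))
  full <- table(factor(classes$class,
                       levels = cocultr:::interaction_class_levels()))
  by_class <- tapply(st$counts$count, st$counts$class, sum)
  expect_equal(as.integer(by_class[names(full)]), as.integer(full))
  expect_error(stratify_interactions(
    transform(classes, species_j = "Z"), calls, envs), "missing")
})

test_that("class enrichment matches the hypergeometric tail by hand", {
  # stratum of 10 records all competition, pool of 20 half competition
  rec <- data.frame(
    species_i = "A", species_j = "B", env = "s1",
    class = c(rep("competition", 10), rep(c("competition", "neutralism"),
                                          c(0, 10))),
    stratum = rep(c("both_growers", "any_non_grower"), each = 10),
    n_sources = 1L, stringsAsFactors = FALSE)
  en <- class_enrichment(list(records = rec), fdr = 0.05,
                         n_sources_bins = NULL)
  row <- en[en$stratum == "both_growers" & en$class == "competition", ]
  # P(X >= 10) drawing 10 from 10 competition + 10 others
  p_hand <- sum(dhyper(10, 10, 10, 10))
  expect_equal(row$p, p_hand, tolerance = 1e-12)
  expect_equal(row$obs_over_exp, 2)
  # class absent from the stratum
  absent <- en[en$stratum == "both_growers" & en$class == "neutralism", ]
  expect_equal(absent$in_stratum, 0L)
  expect_gte(absent$p, 1 - 1e-12)
  # identical composition in both strata: nothing significant
  rec2 <- rec
  rec2$class <- rep(c("competition", "neutralism"), 10)
  en2 <- class_enrichment(list(records = rec2), n_sources_bins = NULL)
  expect_true(all(!en2$enriched))
})
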