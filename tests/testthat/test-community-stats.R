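test_that("Monte-Carlo chi-square is calibrated against references", {
  # identical rows: no heterogeneity at all
  tab <- matrix(c(5, 5, 5, 5), 2, 2)
  res <- chisq_mc(tab, iterations = 500, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # perfectly separated 2x2 table: p at the resolution floor
  sep <- matrix(c(20, 0, 0, 20), 2, 2)
  res2 <- chisq_mc(sep, iterations = 1e4, seed = 1)
  fisher <- fisher.test(sep)$p.value
  expect_lt(res2$p, 5 / (1 + 1e4))
  expect_lt(fisher, 1e-9) # the exact reference agrees it is extreme

  # moderate table: MC p within 3 MC standard errors of R's own
  # both-margins-fixed simulation and near the asymptotic p
  set.seed(42)
  tab3 <- matrix(rpois(12, 30), 3, 4) + 1
  res3 <- chisq_mc(tab3, iterations = 2e4, seed = 7)
  ref <- suppressWarnings(
    chisq.test(tab3, simulate.p.value = TRUE, B = 2e4))
  se <- sqrt(res3$p * (1 - res3$p) / 2e4)
  expect_lt(abs(res3$p - ref$p.value), 3 * se + 3 * se)
  asym <- suppressWarnings(chisq.test(tab3)$p.value)
  expect_lt(abs(res3$p - asym), 0.05 + 3 * se)

  # zero margins dropped with a warning
  tab4 <- rbind(c(3, 0, 4), c(5, 0, 2))
  expect_warning(chisq_mc(tab4, 100, 1), "zero-margin")
  expect_error(suppressWarnings(chisq_mc(matrix(c(3, 4), 1, 2), 10, 1)),
               "at least 2x2")
})

test_that("chi-square MC p is reproducible and bounded below", {
  tab <- matrix(c(12, 3, 4, 11), 2, 2)
  a <- chisq_mc(tab, 2000, seed = 5)
  b <- chisq_mc(tab, 2000, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 2001)
})

test_that("PERMANOVA pseudo-F equals ANOVA F in one dimension", {
  set.seed(8)
  y <- c(rnorm(5, 0), rnorm(6, 1.5))
  g <- rep(c("a", "b"), c(5, 6))
  d2 <- as.matrix(dist(y))^2
  f_perm <- cocultr:::permanova_F(d2, g)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(f_perm, f_aov, tolerance = 1e-10)
})

test_that("pairwise PERMANOVA: exact enumeration, planting, degeneracy", {
  # two categories with identical per-environment profiles: no signal
  part <- data.frame(source = paste0("s", 1:6),
                     category = rep(c("x", "y"), each = 3))
  tm0 <- matrix(1, 6, 4,
                dimnames = list(paste0("s", 1:6), paste0("p", 1:4)))
  r0 <- pairwise_permanova(tm0, part, permutations = 99, seed = 1)
  expect_equal(r0$p, 1)

  # 3 vs 3 environments: p equals full enumeration of the 20 label
  # assignments, computed here independently
  set.seed(12)
  tm <- matrix(rnorm(6 * 4), 6, 4,
               dimnames = list(paste0("s", 1:6), paste0("p", 1:4)))
  tm[1:3, ] <- tm[1:3, ] + 2
  res <- pairwise_permanova(tm, part, permutations = 99, seed = 1)
  expect_equal(res$method, "exact")
  d2 <- as.matrix(dist(tm))^2
  fstat <- function(ix) {
    g <- rep("y", 6); g[ix] <- "x"
    cocultr:::permanova_F(d2, g)
  }
  f_all <- apply(combn(6, 3), 2, fstat)
  f_obs <- fstat(1:3)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(f_all >= f_obs - 1e-12))

  # planted separation is detected after BH
  part3 <- data.frame(source = paste0("s", 1:12),
                      category = rep(c("x", "y", "z"), each = 4))
  set.seed(4)
  tm3 <- matrix(rnorm(12 * 5, sd = 0.5), 12, 5,
                dimnames = list(paste0("s", 1:12), paste0("p", 1:5)))
  tm3[1:4, ] <- tm3[1:4, ] + 3
  res3 <- pairwise_permanova(tm3, part3, permutations = 999, seed = 1)
  expect_true(all(res3$q[res3$category_1 == "x" |
                           res3$category_2 == "x"] < 0.05))
  # a category with one environment is skipped with a warning
  part4 <- data.frame(source = paste0("s", 1:6),
                      category = c(rep("x", 3), rep("y", 2), "z"))
  expect_warning(pairwise_permanova(tm, part4, 99, 1), "skipping")
})

test_that("PERMANOVA pseudo-F matches vegan on multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(31)
  tm <- matrix(rnorm(8 * 6), 8, 6,
               dimnames = list(paste0("s", 1:8), paste0("p", 1:6)))
  grp <- rep(c("x", "y"), each = 4)
  d2 <- as.matrix(dist(tm))^2
  f_mine <- cocultr:::permanova_F(d2, grp)
  fit <- vegan::adonis2(dist(tm) ~ grp, permutations = 2)
  expect_equal(f_mine, fit$F[1], tolerance = 1e-10)
})

test_that("species rank enrichment has exact small-sample behaviour", {
  # all theta equal: every species p = 1 through mid-ranks
  pt <- data.frame(species_i = c("A", "A", "A", "B", "B", "C"),
                   species_j = c("B", "C", "D", "C", "D", "D"),
                   theta = rep(5, 6))
  r <- species_rank_enrichment(pt, seed = 1)
  expect_true(all(r$p == 1))

  # species A's three pairs hold the top three theta values:
  # one-sided tail is 1/20, the two-sided report doubles it
  pt2 <- pt
  pt2$theta <- c(10, 9, 8, 1, 2, 3) # A's pairs are rows 1-3
  r2 <- species_rank_enrichment(pt2, seed = 1)
  a <- r2[r2$species == "A", ]
  expect_equal(a$method, "exact")
  expect_equal(a$mean_rank, mean(rank(pt2$theta)[1:3]))
  expect_equal(a$p, 2 * (1 / 20))
  expect_equal(a$direction, 1)

  # deterministic under a fixed seed in sampled mode
  set.seed(99)
  pt3 <- data.frame(
    species_i = rep(letters[1:9], times = 9:1),
    species_j = unlist(lapply(1:9, function(i) letters[(i + 1):10])),
    theta = rnorm(45))
  s1 <- species_rank_enrichment(pt3, permutations = 500, seed = 3,
                                exhaustive_limit = 10)
  s2 <- species_rank_enrichment(pt3, permutations = 500, seed = 3,
                                exhaustive_limit = 10)
  expect_identical(s1, s2)
  expect_true(all(s1$method == "sampled"))
})

test_that("Spearman trend matches the rank-then-Pearson definition", {
  x <- c(1, 2, 4, 8, 16)
  y <- c(50, 20, 10, 0, -30)
  r <- spearman_trend(x, y)
  expect_equal(r$rho, -1)
  expect_equal(r$p, 0)
  expect_true(is.na(spearman_trend(rep(2, 5), y)$rho))
  set.seed(17)
  x2 <- sample(rep(c(1, 2, 4, 8, 16), each = 20))
  y2 <- -0.3 * x2 + rnorm(100, sd = 4)
  r2 <- spearman_trend(x2, y2)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman",
                                   exact = FALSE))
  expect_equal(r2$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-9)
  expect_error(spearman_trend(1:2, 1:2), "three")
})

test_that("class count tables cross-tabulate correctly", {
  classes <- data.frame(
    species_i = c("A", "A", "B"), species_j = c("B", "C", "C"),
    env = c("s1", "s1", "s2"),
    class = c("competition", "mutualism", "competition"))
  m <- class_count_table(classes, "environment")
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(m["s1", "competition"], 1L)
  expect_equal(sum(m), 3L)
  mp <- class_count_table(classes, "pair")
  expect_equal(rownames(mp), c("A-B", "A-C", "B-C"))
})
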