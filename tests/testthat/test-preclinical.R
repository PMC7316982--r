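test_that("Fisher's exact test matches enumeration and closed forms", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2))$p.value, 1)
  expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  t1 <- matrix(c(5, 2, 1, 4), 2, byrow = TRUE)
  expect_equal(fisherExact2x2(t1)$p.value, enumerate_fisher_p(t1))
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisherExact2x2(matrix(c(0, 0, 1, 1), 2)), "margins")
})

test_that("Kaplan-Meier curve reproduces the product-limit closed form", {
  mo <- data.frame(
    mouse_id = paste0("m", 1:4), arm = "a", aneurysm = TRUE,
    rupture = TRUE, onset_day = c(2, 5, 9, 14), censored = FALSE)
  km <- kmCurve(mo, "a")
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$time, c(2, 5, 9, 14))

  # all censored: survival identically 1
  mo2 <- transform(mo, rupture = FALSE, onset_day = 21, censored = TRUE)
  km2 <- kmCurve(mo2, "a")
  expect_true(all(km2$survival == 1))

  # mixed censoring, hand-computed risk sets:
  # events at 3 (n=5) and 8 (n=3): S = 4/5, then 4/5 * 2/3 = 8/15
  mo3 <- data.frame(
    mouse_id = paste0("m", 1:5), arm = "a", aneurysm = TRUE,
    rupture = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    onset_day = c(3, 6, 8, 21, 21),
    censored = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  km3 <- kmCurve(mo3, "a")
  expect_equal(km3$survival[km3$n_event > 0], c(4 / 5, 8 / 15))
  expect_error(kmCurve(mo3, "missing_arm"), "no aneurysm-positive")
})

test_that("log-rank test is null on identical arms, powered on split ones", {
  base <- data.frame(
    mouse_id = paste0("m", 1:6), aneurysm = TRUE, rupture = TRUE,
    onset_day = c(2, 5, 9, 2, 5, 9), censored = FALSE,
    arm = rep(c("a", "b"), each = 3))
  res <- logrankTest(base)
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)

  arms <- data.frame(label = c("fast", "slow"), n = 40,
                     p_aneurysm = 1, p_rupture = c(0.9, 0.2))
  mo <- simulateMouseExperiment(arms, seed = 101)
  expect_lt(logrankTest(mo)$p.value, 0.01)

  none <- transform(base, rupture = FALSE, onset_day = 21, censored = TRUE)
  expect_warning(res0 <- logrankTest(none), "vacuous|no events")
  expect_equal(res0$p.value, 1)
})

test_that("log-rank statistic is invariant to a common shift of event days", {
  arms <- data.frame(label = c("x", "y"), n = 15, p_aneurysm = 1,
                     p_rupture = c(0.8, 0.4))
  mo <- simulateMouseExperiment(arms, seed = 102)
  s1 <- logrankTest(mo)$statistic
  mo$onset_day <- mo$onset_day + 100
  expect_equal(logrankTest(mo)$statistic, s1)
})

test_that("group comparisons reproduce their textbook behaviour", {
  g <- rep(c("a", "b"), each = 4)
  same <- rep(c(1, 2, 3, 4), 2)
  tt <- groupCompare(same, g, "t_test")
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)

  mw <- groupCompare(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                     "mann_whitney_exact")
  expect_equal(mw$p.value, 1 / 3)   # shared oracle with the rank-sum test

  withr::with_seed(103, {
    v <- rnorm(30); grp3 <- rep(c("a", "b", "c"), each = 10)
  })
  res <- groupCompare(v, grp3, "anova_bonferroni")
  expect_s3_class(res$anova, "htest")
  ref <- summary(aov(v ~ factor(grp3)))[[1]][["Pr(>F)"]][1]
  expect_equal(res$anova$p.value, ref)
  expect_true(all(res$pairwise <= 1, na.rm = TRUE))
  expect_error(groupCompare(v, grp3, "t_test"), "exactly 2")
})

test_that("hypergeometric enrichment agrees with closed forms", {
  uni <- paste0("g", 1:10)
  res <- hypergeomEnrichment(uni[1:5], list(T1 = uni[1:5], Tall = uni), uni)
  expect_equal(res$p[res$term_id == "T1"], 1 / 252)  # C(5,5)C(5,0)/C(10,5)
  expect_equal(res$p[res$term_id == "Tall"], 1)      # term = universe
  res0 <- hypergeomEnrichment(uni[1:3], list(T2 = uni[9:10]), uni)
  expect_gte(res0$p[1], 0.4)                         # zero overlap
  expect_error(hypergeomEnrichment(c("zz"), list(T1 = uni[1:2]), uni),
               "universe")
  expect_error(hypergeomEnrichment(uni[1], list(T1 = uni[1]), character()),
               "empty")
})

test_that("DEG set exclusion performs plain set arithmetic", {
  a <- paste0("g", 1:100)
  b <- c(paste0("g", 81:100), "x1", "x2")
  res <- degSetExclusion(a, b)
  expect_equal(res$size, 80)
  expect_setequal(res$genes, paste0("g", 1:80))
  expect_equal(degSetExclusion(a, "none")$size, 100)
  expect_equal(degSetExclusion(a, a)$size, 0)
})
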