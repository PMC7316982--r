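sep_data <- function(n = 40, p = 10, shift = 3, seed = 71) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
    y <- rep(c("control", "case"), each = n / 2)
    X[y == "case", 1] <- X[y == "case", 1] + shift
    list(X = X, y = y)
  })
}

test_that("single-variable PLS matches the least-squares slope", {
  withr::with_seed(72, {
    x <- matrix(rnorm(40), 40, 1)
    y <- as.numeric(x + rnorm(40, 0, 0.5) > 0)
    fit <- plsdaFit(x, y, n_components = 1)
    expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x))[2]))
    expect_equal(predict(fit, x),
                 unname(fitted(lm(y ~ x))), tolerance = 1e-10)
  })
})

test_that("NIPALS scores are mutually orthogonal", {
  d <- sep_data(p = 8)
  fit <- plsdaFit(d$X, d$y, n_components = 3)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("separable data trains to perfect accuracy", {
  d <- sep_data(shift = 6)
  fit <- plsdaFit(d$X, d$y, n_components = 2)
  expect_equal(mean(predict(fit, d$X, type = "class") == d$y), 1)
})

test_that("NIPALS weights agree with the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  d <- sep_data(n = 40, p = 5, shift = 2, seed = 73)
  fit <- plsdaFit(d$X, d$y, n_components = 2)
  ref <- mixOmics::plsda(d$X, d$y, ncomp = 2, scale = FALSE)
  for (a in 1:2) {
    w1 <- fit$weights[, a]
    w2 <- ref$loadings$X[, a]
    expect_lt(min(max(abs(w1 - w2)), max(abs(w1 + w2))), 1e-8)
  }
})

test_that("PLS-DA rejects degenerate inputs", {
  d <- sep_data()
  expect_error(plsdaFit(d$X, rep("case", nrow(d$X))), "binary|both classes")
  expect_error(plsdaFit(d$X, d$y, n_components = 100), "rank")
  Xz <- d$X; Xz[, 2] <- 5
  expect_warning(fit <- plsdaFit(Xz, d$y), "zero-variance")
  expect_equal(unname(fit$coefficients[2]), 0)
})

test_that("the stability statistic matches a direct two-pass oracle", {
  d <- sep_data(n = 30, p = 5)
  cfg <- mcConfig(30, N = 50, seed = 9)
  st <- mcStability(d$X, d$y, cfg)
  B <- st@betaResamples
  expect_equal(dim(B), c(50, 5))
  # independent two-pass mean/sd recomputation, per the defining formulas
  for (j in seq_len(ncol(B))) {
    bj <- mean(B[, j])
    sj <- sqrt(sum((B[, j] - bj)^2) / (nrow(B) - 1))
    expect_equal(st@betaMean[[j]], bj)
    expect_equal(st@betaSd[[j]], sj)
    if (sj > 0) expect_equal(st@c[[j]], bj / sj)
  }
})

test_that("c_j is invariant to positive rescaling of the predictors", {
  d <- sep_data(n = 30, p = 4)
  cfg <- mcConfig(30, N = 40, seed = 10)
  c1 <- stabilityC(mcStability(d$X, d$y, cfg))
  # global rescaling: beta and s(beta) scale together, c exactly unchanged
  c2 <- stabilityC(mcStability(d$X * 37, d$y, cfg))
  expect_equal(c1, c2, tolerance = 1e-8)
  # single-variable model: per-column rescaling is exactly neutral too
  x1 <- d$X[, 1, drop = FALSE]
  cfg1 <- mcConfig(30, n_components = 1, N = 40, seed = 10)
  expect_equal(stabilityC(mcStability(x1, d$y, cfg1)),
               stabilityC(mcStability(x1 * 37, d$y, cfg1)),
               tolerance = 1e-8)
})

test_that("the Monte-Carlo pipeline is bit-reproducible under a fixed seed", {
  d <- sep_data(n = 24, p = 6)
  cfg <- mcConfig(24, N = 30, seed = 11)
  s1 <- mcStability(d$X, d$y, cfg)
  s2 <- mcStability(d$X, d$y, cfg)
  expect_identical(s1@betaResamples, s2@betaResamples)
  r1 <- cutoffScan(s1, d$X, d$y, cfg)
  r2 <- cutoffScan(s2, d$X, d$y, cfg)
  expect_identical(selectedVariables(r1), selectedVariables(r2))
  expect_identical(accuracyByCutoff(r1), accuracyByCutoff(r2))
})

test_that("a constant variable is flagged undefined and never selected", {
  d <- sep_data(n = 30, p = 5)
  Xc <- cbind(d$X, const = 1)
  cfg <- mcConfig(30, N = 40, seed = 12)
  st <- suppressWarnings(mcStability(Xc, d$y, cfg))
  expect_true(is.na(stabilityC(st)["const"]))
  st <- suppressWarnings(cutoffScan(st, Xc, d$y, cfg))
  expect_false("const" %in% selectedVariables(st))
})

test_that("cutoff grid endpoints behave as documented", {
  d <- sep_data(n = 30, p = 5)
  cfg <- mcConfig(30, N = 40, seed = 13)
  st <- mcStability(d$X, d$y, cfg)
  cs <- abs(stabilityC(st))
  # a cutoff below min |c| keeps every variable at that grid point
  cfg_lo <- mcConfig(30, N = 40, cutoff_grid = c(min(cs) / 2), seed = 13)
  scan_lo <- cutoffScan(st, d$X, d$y, cfg_lo)
  expect_equal(accuracyByCutoff(scan_lo)$n_vars, ncol(d$X))
  # a cutoff above max |c| is skipped; all-above errors
  cfg_mix <- mcConfig(30, N = 40,
                      cutoff_grid = c(min(cs) / 2, max(cs) + 1), seed = 13)
  expect_equal(nrow(accuracyByCutoff(cutoffScan(st, d$X, d$y, cfg_mix))), 1)
  cfg_hi <- mcConfig(30, N = 40, cutoff_grid = c(max(cs) + 1), seed = 13)
  expect_error(cutoffScan(st, d$X, d$y, cfg_hi), "empties")
})

test_that("noise variables score lower than a planted discriminator", {
  d <- sep_data(n = 60, p = 20, shift = 2, seed = 77)
  cfg <- mcConfig(60, N = 200, seed = 14)
  st <- mcStability(d$X, d$y, cfg)
  cs <- abs(stabilityC(st))
  expect_equal(unname(which.max(cs)), 1)
  expect_gt(cs[1], mean(cs[-1]))
  scan <- cutoffScan(st, d$X, d$y, cfg)
  expect_true("v01" %in% selectedVariables(scan))
})

test_that("under a global null the CV accuracy stays near chance", {
  withr::with_seed(78, {
    X <- matrix(rnorm(60 * 10), 60, 10)
    y <- rep(c("control", "case"), each = 30)
  })
  cfg <- mcConfig(60, N = 100, cutoff_grid = c(0.1, 0.5), seed = 15)
  st <- mcStability(X, y, cfg)
  scan <- cutoffScan(st, X, y, cfg)
  expect_lt(abs(max(accuracyByCutoff(scan)$accuracy) - 0.5), 0.2)
})

test_that("mcConfig enforces its invariants", {
  expect_error(mcConfig(10, M = 10), "M must")
  expect_error(mcConfig(10, N = 1), "N must")
  expect_error(mcConfig(10, cutoff_grid = c(2, 1)), "ascending")
})
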