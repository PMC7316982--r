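#' PLS-DA fit by NIPALS
#'
#' Partial least squares against a centered 0/1 dummy response (PLS1).
#' Components are extracted by NIPALS: weights from the covariance of the
#' deflated predictors with the response residual, orthogonal score
#' vectors, and the composite regression coefficient
#' \eqn{\beta = W (P'W)^{-1} q}. Prediction thresholds the continuous score
#' at the class-code midpoint (0.5).
#'
#' @param X sample-by-variable numeric matrix.
#' @param y binary labels (factor, character, or 0/1); both classes
#'   required.
#' @param n_components latent components (must not exceed `rank(X)`).
#' @return object of class `plsda` with coefficients, intercept, scores,
#'   loadings, weights, the class coding, and training metadata.
#' @export
plsdaFit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y01 <- .as_binary(y)
  if (length(unique(y01$y)) < 2) stop("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p)) {
    stop("n_components exceeds the rank bound min(n - 1, p)")
  }
  xbar <- colMeans(X)
  E <- sweep(X, 2, xbar)
  zero_var <- apply(E, 2, function(v) all(abs(v) < 1e-12))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance column(s); coefficients set to 0")
  }
  ybar <- mean(y01$y)
  f <- y01$y - ybar
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  qv <- numeric(0)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    w[zero_var] <- 0
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break   # response residual exhausted
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W <- cbind(W, w); P <- cbind(P, p_); Tm <- cbind(Tm, t_)
    qv <- c(qv, q_)
  }
  if (ncol(W) == 0) {
    beta <- rep(0, p)
  } else {
    beta <- as.vector(W %*% solve(crossprod(P, W), qv))
  }
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 intercept = ybar - sum(xbar * beta),
                 scores = Tm, loadings = P, weights = W, q = qv,
                 levels = y01$levels, n_components = ncol(W)),
            class = "plsda")
}

.as_binary <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    list(y = as.numeric(y), levels = c("0", "1"))
  } else {
    f <- as.factor(y)
    if (nlevels(f) != 2) stop("y must be binary")
    list(y = as.numeric(f) - 1, levels = levels(f))
  }
}

#' Predict from a PLS-DA fit
#'
#' @param object a `plsda` fit.
#' @param newdata sample-by-variable matrix.
#' @param type `"score"` for the continuous response or `"class"` for the
#'   0.5-thresholded label.
#' @param ... unused.
#' @return numeric scores or a character vector of labels.
#' @export
predict.plsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- as.vector(as.matrix(newdata) %*% object$coefficients +
                   object$intercept)
  if (type == "score") s else object$levels[(s > 0.5) + 1]
}

#' Monte-Carlo configuration for stability selection
#'
#' @param n n training samples (used for the M and N defaults).
#' @param n_components PLS components (default 2).
#' @param M resample size; default `floor(n/2)` (half of the samples).
#' @param N number of Monte-Carlo resamples; default `min(n^2, cap)`. The
#'   n-squared prescription is statistically comfortable but quadratic in
#'   cohort size, so a configurable ceiling keeps desk-scale runtimes; raise
#'   `cap` to recover the full n^2.
#' @param cap ceiling for `N` (default 2000).
#' @param cutoff_grid ascending |c| cutoffs scanned for the selection.
#' @param k_folds cross-validation folds in the cutoff scan (default 4).
#' @param seed integer seed.
#' @return an `McConfig` list.
#' @export
mcConfig <- function(n, n_components = 2, M = floor(n / 2),
                     N = min(n^2, cap), cap = 2000,
                     cutoff_grid = seq(0.5, 5, by = 0.5),
                     k_folds = 4, seed = 1L) {
  if (M < 1 || M >= n) stop("M must satisfy 1 <= M < n")
  if (N < 2) stop("N must be >= 2")
  if (!length(cutoff_grid) || is.unsorted(cutoff_grid)) {
    stop("cutoff_grid must be nonempty and ascending")
  }
  structure(list(n = n, n_components = n_components, M = M, N = N,
                 cutoff_grid = cutoff_grid, k_folds = k_folds,
                 seed = as.integer(seed)),
            class = "McConfig")
}

#' Monte-Carlo PLS-DA coefficient stability
#'
#' Draws `N` class-stratified resamples of size `M` without replacement,
#' fits a PLS-DA on each, and summarises each variable's coefficient stream
#' \eqn{\beta_{ij}} by its mean \eqn{\beta_j}, its spread
#' \eqn{s(\beta_j) = (\sum_i (\beta_{ij} - \beta_j)^2 / (N-1))^{1/2}},
#' and the stability statistic \eqn{c_j = \beta_j / s(\beta_j)}. Variables
#' whose spread is exactly zero get `c = NA` and are excluded from
#' selection. `c_j` is scale-free: rescaling a column rescales mean and
#' spread together.
#'
#' @param X sample-by-variable matrix.
#' @param y binary labels.
#' @param config an [mcConfig()] for `nrow(X)` samples.
#' @return a [StabilityResult-class] (selection empty until
#'   [cutoffScan()]).
#' @export
mcStability <- function(X, y, config = mcConfig(nrow(X))) {
  X <- as.matrix(X)
  y01 <- .as_binary(y)$y
  n <- nrow(X)
  stopifnot(config$M < n)
  idx_case <- which(y01 == 1)
  idx_ctrl <- which(y01 == 0)
  m_case <- max(1L, min(length(idx_case) - 0L,
                        round(config$M * length(idx_case) / n)))
  m_case <- min(m_case, config$M - 1L)   # leave room for the other class
  m_ctrl <- config$M - m_case
  if (m_ctrl > length(idx_ctrl) || m_case > length(idx_case)) {
    stop("resample size incompatible with class sizes")
  }
  B <- with_substream(config$seed, 31L, {
    vapply(seq_len(config$N), function(i) {
      idx <- c(sample(idx_case, m_case), sample(idx_ctrl, m_ctrl))
      fit <- suppressWarnings(
        plsdaFit(X[idx, , drop = FALSE], y01[idx],
                 n_components = config$n_components))
      fit$coefficients
    }, numeric(ncol(X)))
  })
  B <- t(matrix(B, nrow = ncol(X)))       # N x p (robust to p = 1)
  colnames(B) <- colnames(X)
  beta_mean <- colMeans(B)
  beta_sd <- apply(B, 2, stats::sd)
  cj <- ifelse(beta_sd > 0, beta_mean / beta_sd, NA_real_)
  new("StabilityResult", betaResamples = B, betaMean = beta_mean,
      betaSd = beta_sd, c = cj, selected = character(),
      accuracyByCutoff = data.frame(), importance = numeric())
}

#' Cross-validated cutoff scan over the stability statistic
#'
#' For each cutoff in the grid, restricts the predictors to variables with
#' `|c_j| > cutoff` and estimates stratified k-fold cross-validation
#' accuracy of a fresh PLS-DA. The winning cutoff maximises mean accuracy;
#' ties resolve to the larger cutoff (fewer variables). Cutoffs that empty
#' the variable set are skipped; if every cutoff does, an error is raised.
#'
#' @param stability a [StabilityResult-class] from [mcStability()].
#' @param X,y the data the stability run used.
#' @param config the same [mcConfig()].
#' @return the `StabilityResult` with `selected`, `accuracyByCutoff`, and
#'   `importance` filled.
#' @export
cutoffScan <- function(stability, X, y, config = mcConfig(nrow(X))) {
  stopifnot(is(stability, "StabilityResult"))
  X <- as.matrix(X)
  y01 <- .as_binary(y)$y
  cj <- stabilityC(stability)
  rows <- list()
  with_substream(config$seed, 43L, {
    for (cut in config$cutoff_grid) {
      vars <- which(!is.na(cj) & abs(cj) > cut)
      if (!length(vars)) next
      fold <- stratified_folds(y01, config$k_folds)
      acc <- vapply(seq_len(config$k_folds), function(k) {
        tr <- fold != k
        fit <- suppressWarnings(
          plsdaFit(X[tr, vars, drop = FALSE], y01[tr],
                   n_components = min(config$n_components, length(vars))))
        pred <- predict.plsda(fit, X[!tr, vars, drop = FALSE],
                              type = "class")
        mean(pred == as.character(y01[!tr]))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cut, accuracy = mean(acc), n_vars = length(vars))
    }
  })
  if (!length(rows)) stop("every cutoff empties the variable set")
  curve <- do.call(rbind, rows)
  best <- curve$cutoff[curve$accuracy >= max(curve$accuracy)]
  best <- max(best)                      # ties -> larger cutoff
  sel <- which(!is.na(cj) & abs(cj) > best)
  sel_names <- if (is.null(colnames(X))) as.character(sel) else
    colnames(X)[sel]
  stability@selected <- sel_names
  stability@accuracyByCutoff <- curve
  stability@importance <- stats::setNames(abs(cj[sel]), sel_names)
  stability
}
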