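#' Random-forest classifier contract
#'
#' The default pluggable learner for [crossValidatedScores()]: a thin
#' wrapper around [randomForest::randomForest] exposing the `fit`/`score`
#' contract (score = out-of-class probability of the case class).
#'
#' @param ntree trees per forest (library default 500).
#' @return list with `fit(X, y)` and `score(model, X)`.
#' @export
rfModel <- function(ntree = 500) {
  list(
    fit = function(X, y) {
      randomForest::randomForest(x = as.data.frame(X), y = as.factor(y),
                                 ntree = ntree)
    },
    score = function(model, X) {
      pr <- stats::predict(model, as.data.frame(X), type = "prob")
      pr[, "case"]
    }
  )
}

#' PLS-DA classifier contract
#'
#' Wraps [plsdaFit()] in the same `fit`/`score` contract, scoring by the
#' continuous PLS response (monotone in the case probability).
#'
#' @param n_components latent components.
#' @return list with `fit(X, y)` and `score(model, X)`.
#' @export
plsdaModel <- function(n_components = 2) {
  list(
    fit = function(X, y) plsdaFit(X, y, n_components = n_components),
    score = function(model, X) {
      s <- predict.plsda(model, X, type = "score")
      if (identical(model$levels[2], "case")) s
      else if (identical(model$levels[1], "case")) -s
      else s
    }
  )
}

#' Repeated stratified cross-validated scoring
#'
#' For each of `n_trials` random trials, draws a fresh stratified
#' `n_folds`-fold split, trains the pluggable classifier on each training
#' fold, and collects continuous out-of-fold scores and per-fold
#' accuracies (score thresholded at 0.5). The per-sample scores averaged
#' across trials feed ROC analysis; the paper-style protocol is 30 trials
#' of 4-fold cross-validation.
#'
#' @param table an [AbundanceTable-class] or sample-by-feature matrix.
#' @param labels case/control labels (taken from the table if omitted).
#' @param model a `fit`/`score` contract, e.g. [rfModel()] (default) or
#'   [plsdaModel()].
#' @param n_folds folds per trial (default 4); must not exceed the smaller
#'   class.
#' @param n_trials random trials (default 30).
#' @param seed integer seed; fixes fold assignments and learner randomness.
#' @return list with `scores` (mean out-of-fold score per sample),
#'   `score_matrix` (sample x trial), `fold_accuracies` (trial x fold),
#'   `mean_accuracy`, and `labels`.
#' @export
crossValidatedScores <- function(table, labels = NULL, model = rfModel(),
                                 n_folds = 4, n_trials = 30, seed = 1L) {
  if (is(table, "AbundanceTable")) {
    X <- t(abundances(table))
    labels <- groupLabels(table)
  } else {
    X <- as.matrix(table)
    if (is.null(labels)) stop("supply labels for a bare matrix")
  }
  labels <- factor(labels, levels = c("control", "case"))
  if (any(table(labels) < n_folds)) {
    stop("n_folds exceeds the smallest class size")
  }
  n <- nrow(X)
  with_substream(seed, 47L, {
    score_matrix <- matrix(NA_real_, n, n_trials)
    acc <- matrix(NA_real_, n_trials, n_folds)
    for (tr in seq_len(n_trials)) {
      fold <- stratified_folds(labels, n_folds)
      for (k in seq_len(n_folds)) {
        train <- fold != k
        fit <- model$fit(X[train, , drop = FALSE], labels[train])
        s <- model$score(fit, X[!train, , drop = FALSE])
        score_matrix[!train, tr] <- s
        acc[tr, k] <- mean((s > 0.5) == (labels[!train] == "case"))
      }
    }
    list(scores = rowMeans(score_matrix), score_matrix = score_matrix,
         fold_accuracies = acc, mean_accuracy = mean(acc),
         labels = as.character(labels))
  })
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with ties grouped; the curve runs
#' from (0, 0) to (1, 1) and the trapezoidal area equals the tie-averaged
#' Mann-Whitney statistic \eqn{U/(n_1 n_2)}.
#'
#' @param scores continuous classifier scores (higher = more case-like).
#' @param labels case/control (or 0/1) labels; both classes required.
#' @return list with `roc_points` (data.frame FPR, TPR) and `auc`.
#' @examples
#' rocAuc(c(3, 1, 2, 0), c("case", "control", "case", "control"))$auc # 1
#' @export
rocAuc <- function(scores, labels) {
  pos <- .case_indicator(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # group tied scores so the curve cuts diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  TPR <- c(0, tp[last] / sum(pos))
  FPR <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(FPR) * (utils::head(TPR, -1) + utils::tail(TPR, -1)) / 2)
  list(roc_points = data.frame(FPR = FPR, TPR = TPR), auc = auc)
}

.case_indicator <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (all(labels %in% c("case", "control"))) return(labels == "case")
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be binary")
  f == levels(f)[2]
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls with replacement (separately, preserving
#' class sizes), recomputes the AUC, and reports the percentile interval.
#'
#' @param scores,labels as in [rocAuc()].
#' @param n_boot bootstrap replicates (>= 100; default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed integer seed.
#' @return named numeric `c(low, high)`.
#' @export
aucBootstrapCI <- function(scores, labels, n_boot = 1000, level = 0.95,
                           seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  pos <- .case_indicator(labels)
  i_pos <- which(pos); i_neg <- which(!pos)
  with_substream(seed, 53L, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i_pos, replace = TRUE), sample(i_neg, replace = TRUE))
      rocAuc(scores[idx], pos[idx])$auc
    }, numeric(1))
    a <- (1 - level) / 2
    stats::setNames(stats::quantile(aucs, c(a, 1 - a), names = FALSE),
                    c("low", "high"))
  })
}
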