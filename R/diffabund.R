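#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks are used for ties. In `"exact"` mode the p-value comes from the
#' exact null distribution of the rank-sum statistic (all
#' \eqn{C(n_1 + n_2, n_1)} assignments); exact mode with ties falls back to
#' the normal approximation with a warning. The normal path applies the
#' tie-corrected variance and, by design, no continuity correction
#' (the `wilcox.test(correct = FALSE)` large-sample convention common in
#' metagenomic pipelines); set `correct = TRUE` to toggle it.
#'
#' @param x,y numeric samples, each nonempty.
#' @param mode `"normal_approx"` (default) or `"exact"`.
#' @param correct apply the continuity correction in the normal path.
#' @return list with `statistic` (the Mann-Whitney U for `x`), `p`
#'   (two-sided), and `mode` actually used.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact") # p = 1/3
#' @export
wilcoxonRankSum <- function(x, y, mode = c("normal_approx", "exact"),
                            correct = FALSE) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (mode == "exact" && has_ties) {
    warning("ties present; falling back to the normal approximation")
    mode <- "normal_approx"
  }
  if (mode == "exact") {
    # exact two-sided p from the null rank-sum distribution
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else if (U < n1 * n2 / 2) {
      2 * stats::pwilcox(U, n1, n2)
    } else 1
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (correct) z <- z - sign(z) * 0.5
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = U, p = p, mode = mode)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j},
#' mapped back to the input order and capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
  assert_probability(p, "p-values")
  stats::p.adjust(p, method = "BH")
}

#' Differential abundance by per-feature Wilcoxon + BH
#'
#' Tests every feature between the two groups with the rank-sum test,
#' adjusts across features with Benjamini-Hochberg, and classifies the
#' direction from group means of relative abundance (medians optionally).
#'
#' @param table an [AbundanceTable-class] with both groups present, or a
#'   feature-by-sample matrix (then supply `groups`).
#' @param alpha_q q-value threshold for the returned marker set.
#' @param groups case/control labels when `table` is a bare matrix.
#' @param direction_stat `"mean"` (default) or `"median"` group summary used
#'   for the enrichment direction.
#' @param all return every feature rather than only those below `alpha_q`.
#' @param min_prevalence optional fraction in `[0, 1]`; features present in
#'   fewer samples are dropped before testing (default 0 = no filter).
#' @return data.frame ordered by (q, feature_id): feature_id, statistic, p,
#'   q, direction, mean_case, mean_control.
#' @export
differentialFeatures <- function(table, alpha_q = 0.05, groups = NULL,
                                 direction_stat = c("mean", "median"),
                                 all = FALSE, min_prevalence = 0) {
  direction_stat <- match.arg(direction_stat)
  if (is(table, "AbundanceTable")) {
    m <- abundances(table)
    groups <- groupLabels(table)
  } else {
    m <- as.matrix(table)
    if (is.null(groups)) stop("supply group labels for a bare matrix")
  }
  if (!all(c("case", "control") %in% groups)) {
    stop("both groups must be present")
  }
  if (min(table(groups)) < 2) stop("need at least 2 samples per group")
  if (min_prevalence > 0) {
    keep <- rowMeans(m > 0) >= min_prevalence
    m <- m[keep, , drop = FALSE]
  }
  case <- groups == "case"
  summ <- if (direction_stat == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  res <- t(apply(m, 1, function(v) {
    w <- wilcoxonRankSum(v[case], v[!case])
    c(w$statistic, w$p)
  }))
  out <- data.frame(
    feature_id = rownames(m),
    statistic = res[, 1],
    p = res[, 2],
    q = bhAdjust(res[, 2]),
    mean_case = summ(m[, case, drop = FALSE]),
    mean_control = summ(m[, !case, drop = FALSE]),
    row.names = NULL
  )
  out$direction <- ifelse(out$mean_case >= out$mean_control,
                          "case_enriched", "control_enriched")
  out <- out[order(out$q, out$feature_id), ]
  rownames(out) <- NULL
  if (all) out else out[out$q < alpha_q, ]
}
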