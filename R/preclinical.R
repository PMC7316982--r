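#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of tables with
#' the observed margins. The two-sided p-value follows the
#' point-probability rule (sum over tables whose probability does not
#' exceed the observed one), the [stats::fisher.test] convention.
#'
#' @param tab 2x2 matrix (rows = arms, columns = outcome yes/no), or the
#'   cell `a` with `b`, `c`, `d` supplied separately.
#' @param b,c,d remaining cells when `tab` is scalar.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return an object of class `htest`.
#' @examples
#' fisherExact2x2(matrix(c(17, 3, 9, 11), 2, byrow = TRUE)) # p ~ 0.019
#' @export
fisherExact2x2 <- function(tab, b = NULL, c = NULL, d = NULL,
                           alternative = "two.sided") {
  if (length(tab) == 1) tab <- matrix(c(tab, b, c, d), 2, byrow = TRUE)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("margins must be positive")
  }
  stats::fisher.test(tab, alternative = alternative)
}

#' Kaplan-Meier symptom-free curve for one arm
#'
#' Product-limit estimator over the aneurysm-positive animals of one arm
#' (matching the figure-legend denominators): events are rupture/symptom
#' onsets, all other animals are right-censored at day 21.
#'
#' @param outcomes data.frame from [simulateMouseExperiment()] (columns
#'   arm, aneurysm, rupture, onset_day).
#' @param arm arm label to extract.
#' @return data.frame with columns time, n_risk, n_event, survival, plus
#'   attribute `"censored"` listing censoring days.
#' @export
kmCurve <- function(outcomes, arm) {
  sub <- outcomes[outcomes$arm == arm & outcomes$aneurysm, , drop = FALSE]
  if (!nrow(sub)) stop("no aneurysm-positive animals in arm '", arm, "'")
  fit <- survival::survfit(
    survival::Surv(sub$onset_day, sub$rupture) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  attr(out, "censored") <- sub$onset_day[!sub$rupture]
  out
}

#' Mantel-Cox log-rank test across arms
#'
#' Compares symptom-onset distributions among aneurysm-positive animals:
#' at each event time the observed events per arm are compared with their
#' hypergeometric expectation; the summed deviations give a chi-square
#' statistic with (number of arms - 1) degrees of freedom. With no events
#' anywhere the test is vacuous and returns p = 1 with a warning.
#'
#' @param outcomes data.frame as in [kmCurve()].
#' @param arms arm labels to compare (default: all arms present).
#' @return an `htest` with statistic, df, and p.value.
#' @export
logrankTest <- function(outcomes, arms = unique(outcomes$arm)) {
  if (length(arms) < 2) stop("need at least two arms")
  sub <- outcomes[outcomes$arm %in% arms & outcomes$aneurysm, , drop = FALSE]
  if (!nrow(sub) || min(table(factor(sub$arm, levels = arms))) < 1) {
    stop("every compared arm needs at least one aneurysm-positive animal")
  }
  res <- list(method = "Mantel-Cox log-rank test",
              data.name = "symptom onset by arm")
  if (!any(sub$rupture)) {
    warning("no events in any arm; log-rank test is vacuous")
    res <- c(res, list(statistic = c(chisq = 0),
                       parameter = c(df = length(arms) - 1), p.value = 1))
    class(res) <- "htest"
    return(res)
  }
  sd <- survival::survdiff(
    survival::Surv(onset_day, rupture) ~ arm, data = sub)
  df <- length(sd$n) - 1
  res <- c(res, list(statistic = c(chisq = sd$chisq),
                     parameter = c(df = df),
                     p.value = stats::pchisq(sd$chisq, df,
                                             lower.tail = FALSE)))
  class(res) <- "htest"
  res
}

#' Two-or-more-group comparison of continuous outcomes
#'
#' `"t_test"`: Student's unpaired two-tailed t test (pooled variance).
#' `"mann_whitney_exact"`: Mann-Whitney U with the exact method.
#' `"anova_bonferroni"`: one-way ANOVA plus Bonferroni-adjusted pairwise
#' t tests (pairwise p multiplied by the number of comparisons, capped at
#' 1).
#'
#' @param values numeric outcome vector.
#' @param groups group label per value.
#' @param method one of `"t_test"`, `"mann_whitney_exact"`,
#'   `"anova_bonferroni"`.
#' @return an `htest` for the two-sample methods; for ANOVA a list with
#'   `anova` (htest) and `pairwise` (matrix of Bonferroni-adjusted p).
#' @export
groupCompare <- function(values, groups,
                         method = c("t_test", "mann_whitney_exact",
                                    "anova_bonferroni")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (method %in% c("t_test", "mann_whitney_exact") && k != 2) {
    stop("two-sample method requires exactly 2 groups")
  }
  if (method == "anova_bonferroni" && k < 3) {
    stop("ANOVA with post hoc comparisons is for more than 2 groups")
  }
  split_v <- split(values, groups)
  switch(method,
    t_test = {
      if (any(vapply(split_v, stats::sd, numeric(1)) == 0) &&
          stats::sd(values) == 0) {
        stop("zero within-group variance")
      }
      stats::t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
    },
    mann_whitney_exact = {
      suppressWarnings(
        stats::wilcox.test(split_v[[1]], split_v[[2]], exact = TRUE,
                           correct = FALSE))
    },
    anova_bonferroni = {
      if (all(vapply(split_v, stats::sd, numeric(1)) == 0)) {
        stop("zero within-group variance")
      }
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      res <- list(method = "One-way ANOVA",
                  data.name = "values by groups",
                  statistic = c(F = an[["F value"]][1]),
                  parameter = c(df1 = an[["Df"]][1], df2 = an[["Df"]][2]),
                  p.value = an[["Pr(>F)"]][1])
      class(res) <- "htest"
      pw <- stats::pairwise.t.test(values, groups,
                                   p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      list(anova = res, pairwise = pw$p.value)
    })
}

#' Hypergeometric enrichment of a gene set against annotation terms
#'
#' Upper-tail hypergeometric test per term:
#' \eqn{P[X \ge k]} for overlap k between the differential set and the
#' term within a fixed universe, BH-adjusted across terms.
#'
#' @param de_set differential gene identifiers (subset of `universe`).
#' @param term_map named list: term id -> gene identifiers.
#' @param universe background gene identifiers.
#' @param alpha_q significance threshold on q (default 0.05).
#' @return data.frame: term_id, overlap, term_size, de_size,
#'   universe_size, p, q, significant; ordered by p.
#' @export
hypergeomEnrichment <- function(de_set, term_map, universe,
                                alpha_q = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_set <- unique(de_set)
  if (!all(de_set %in% universe)) stop("de_set must lie within the universe")
  N <- length(universe)
  nde <- length(de_set)
  rows <- lapply(names(term_map), function(tid) {
    term <- intersect(unique(term_map[[tid]]), universe)
    k <- length(intersect(term, de_set))
    m <- length(term)
    p <- stats::phyper(k - 1, m, N - m, nde, lower.tail = FALSE)
    data.frame(term_id = tid, overlap = k, term_size = m, de_size = nde,
               universe_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out$significant <- out$q < alpha_q
  out[order(out$p, out$term_id), ]
}

#' Exclude shared genes from a differential set
#'
#' Returns the genes specific to `set_a` (i.e. `a` minus the intersection
#' with `set_b`) and their count — the set arithmetic used to isolate
#' condition-specific differentially expressed genes.
#'
#' @param set_a,set_b identifier vectors.
#' @return list with `genes` and `size`.
#' @examples
#' degSetExclusion(letters[1:5], letters[4:6])$size # 3
#' @export
degSetExclusion <- function(set_a, set_b) {
  genes <- setdiff(unique(set_a), set_b)
  list(genes = genes, size = length(genes))
}
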