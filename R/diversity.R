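#' Rarefaction curve by repeated random subsampling
#'
#' For each requested subsample size, draws `n_repeats` random subsamples of
#' reads without replacement from the pooled gene counts and reports the
#' mean number of distinct genes observed. The Monte-Carlo mean converges on
#' the hypergeometric closed form
#' \eqn{\sum_i (1 - C(N - N_i, m)/C(N, m))}.
#'
#' @param counts nonnegative integer vector of per-gene read counts (a
#'   gene-by-sample matrix is pooled by row sums).
#' @param subsample_sizes read depths to rarefy to; each must not exceed the
#'   pooled total.
#' @param n_repeats random subsamples per size (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `size` and `richness` (mean distinct
#'   genes).
#' @examples
#' rarefactionCurve(c(5, 3, 2), c(0, 4, 10), n_repeats = 50, seed = 1)
#' @export
rarefactionCurve <- function(counts, subsample_sizes, n_repeats = 100,
                             seed = 1L) {
  if (is.matrix(counts)) counts <- rowSums(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  total <- sum(counts)
  if (any(subsample_sizes > total)) {
    stop("subsample size exceeds the pooled read count")
  }
  pool <- rep.int(seq_along(counts), counts)
  with_substream(seed, 7L, {
    rich <- vapply(subsample_sizes, function(m) {
      if (m == 0) return(0)
      mean(vapply(seq_len(n_repeats), function(r) {
        length(unique(pool[sample.int(total, m)]))
      }, numeric(1)))
    }, numeric(1))
    data.frame(size = subsample_sizes, richness = rich)
  })
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} over the positive entries of the
#' renormalised abundance vector. The default base 2 follows the QIIME v1
#' convention; pass `base = exp(1)` for the vegan dialect.
#'
#' @param x nonnegative abundance vector with positive sum.
#' @param base logarithm base (default 2).
#' @return the Shannon index.
#' @examples
#' shannonIndex(c(0.5, 0.25, 0.25)) # 1.5
#' @export
shannonIndex <- function(x, base = 2) {
  if (any(x < 0)) stop("abundances must be nonnegative")
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all
#' sample pairs (columns). Pairs of all-zero samples are undefined and
#' returned as `NaN` with a warning.
#'
#' @param x an [AbundanceTable-class] or a feature-by-sample matrix.
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "AbundanceTable")) abundances(x) else as.matrix(x)
  if (any(m < 0)) stop("abundances must be nonnegative")
  zero <- colSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (any(zero)) {
    d[zero, zero] <- NaN
    diag(d) <- 0
    warning("all-zero samples produce undefined Bray-Curtis pairs (NaN)")
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-d^2/2} and
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues are reported
#' but their axes dropped, with no Cailliez/Lingoes correction.
#'
#' @param d square symmetric zero-diagonal distance matrix.
#' @return list with `coordinates` (sample-by-axis), `eigenvalues` (all,
#'   descending), and `proportion_explained` (positive eigenvalues over the
#'   sum of absolute eigenvalues, so the proportions sum to at most 1).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(eig > max(abs(eig)) * 1e-10)
  if (npos == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PCo1"))
    prop <- 0
  } else {
    coords <- fit$points[, seq_len(npos), drop = FALSE]
    colnames(coords) <- paste0("PCo", seq_len(npos))
    rownames(coords) <- rownames(d)
    prop <- eig[seq_len(npos)] / sum(abs(eig))
  }
  list(coordinates = coords, eigenvalues = eig, proportion_explained = prop)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix: all pairwise dissimilarities are ranked jointly and
#' \eqn{R = (\bar r_B - \bar r_W)/(M/2)} with \eqn{M = n(n-1)/2}. The
#' permutation p-value uses the add-one correction
#' \eqn{p = (\#\{R^* \ge R\} + 1)/(n_{perm} + 1)}, so p is never zero.
#' Because R depends on the dissimilarities only through their ranks it is
#' invariant under monotone transforms of the distances.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param groups group label per sample; at least two groups of two.
#' @param n_permutations label permutations (default 999).
#' @param seed integer seed.
#' @return list with `R`, `p`, `n_permutations`, and the vector of permuted
#'   statistics `permuted`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  n <- nrow(d)
  stopifnot(length(groups) == n)
  pair <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  M <- length(r)
  stat <- function(g) {
    between <- g[pair[, 1]] != g[pair[, 2]]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R_obs <- stat(groups)
  with_substream(seed, 13L, {
    perm <- vapply(seq_len(n_permutations),
                   function(i) stat(sample(groups)), numeric(1))
    p <- (sum(perm >= R_obs) + 1) / (n_permutations + 1)
    list(R = R_obs, p = p, n_permutations = n_permutations, permuted = perm)
  })
}
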