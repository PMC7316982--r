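#' SparCC configuration
#'
#' Defaults follow the original SparCC release: 20 strong-pair exclusion
#' iterations at threshold 0.1, 20 Dirichlet resamplings, 100 permutations
#' for the pseudo p-values.
#'
#' @param n_exclusion_iterations maximum strongly-correlated pairs excluded
#'   while re-solving the basis system.
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded, in (0, 1).
#' @param n_dirichlet_draws posterior fraction resamplings (used when the
#'   input is integer counts; fractional input is used as-is in one draw).
#' @param n_permutations permutations for [sparccPseudoP()].
#' @param seed integer seed.
#' @return a `SparccConfig` list.
#' @export
sparccConfig <- function(n_exclusion_iterations = 20,
                         exclusion_threshold = 0.1,
                         n_dirichlet_draws = 20,
                         n_permutations = 100,
                         seed = 1L) {
  if (exclusion_threshold <= 0 || exclusion_threshold >= 1) {
    stop("exclusion_threshold must lie in (0, 1)")
  }
  if (n_exclusion_iterations < 1 || n_dirichlet_draws < 1 ||
      n_permutations < 1) {
    stop("iteration counts must be >= 1")
  }
  structure(list(n_exclusion_iterations = n_exclusion_iterations,
                 exclusion_threshold = exclusion_threshold,
                 n_dirichlet_draws = n_dirichlet_draws,
                 n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "SparccConfig")
}

# One SparCC basis-correlation estimate from a fraction matrix
# (features x samples). Solves the sparsity-assumption linear system for the
# basis variances, iteratively excluding the strongest pair above the
# threshold and re-solving.
.sparcc_one <- function(frac, n_excl, thresh) {
  D <- nrow(frac)
  L <- log(frac)
  C <- stats::cov(t(L))
  v <- diag(C)
  # T[i, j] = Var(log(x_i / x_j)) = v_i + v_j - 2 cov_ij
  Tm <- outer(v, v, "+") - 2 * C
  include <- matrix(TRUE, D, D)
  diag(include) <- FALSE
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  rho <- NULL
  for (iter in seq_len(n_excl + 1L)) {
    t_i <- rowSums(Tm * include)
    omega <- solve(M, t_i)
    omega <- pmax(omega, .Machine$double.eps)
    denom <- 2 * sqrt(outer(omega, omega))
    rho <- (outer(omega, omega, "+") - Tm) / denom
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (iter > n_excl) break
    cand <- abs(rho)
    cand[!include] <- -Inf
    # keep every feature solvable: at least 3 included partners
    deg <- rowSums(include)
    cand[deg <= 3, ] <- -Inf
    cand[, deg <= 3] <- -Inf
    m <- max(cand)
    if (!is.finite(m) || m <= thresh) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    include[i, j] <- include[j, i] <- FALSE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
  }
  rho
}

#' SparCC basis correlations for compositional data
#'
#' Estimates the correlations of the unobserved basis abundances from
#' relative abundances via log-ratio variances
#' \eqn{t_{ij} = Var(\log(x_i/x_j))}: under the sparsity assumption the
#' basis variances \eqn{\omega} solve a linear system in the row sums of
#' \eqn{t}, and \eqn{\rho_{ij} = (\omega_i + \omega_j - t_{ij}) /
#' (2\sqrt{\omega_i \omega_j})}, clipped to \eqn{[-1, 1]}. The strongest
#' pair above the exclusion threshold is iteratively removed from the
#' system and the solution refined. Integer count input is resampled
#' `n_dirichlet_draws` times from per-sample Dirichlet(count + 1)
#' posteriors and the element-wise median returned; fractional input is
#' closure-normalised and estimated in a single pass. The estimate is
#' invariant to per-sample closure by construction (log-ratios cancel the
#' sample total).
#'
#' @param x feature-by-sample matrix of counts or fractions; at least 4
#'   features (the basis-variance system is underdetermined below that) and
#'   no zero-variance feature.
#' @param config a [sparccConfig()].
#' @return feature-by-feature basis correlation matrix (unit diagonal).
#' @export
sparccCorrelation <- function(x, config = sparccConfig()) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("SparCC needs at least 4 features")
  if (any(x < 0)) stop("abundances must be nonnegative")
  is_counts <- all(x == round(x)) && max(x) > 1
  if (!is_counts) {
    frac <- sweep(x, 2, colSums(x), "/")
    if (any(frac == 0)) {
      pc <- min(frac[frac > 0]) / 2
      frac <- sweep(frac + pc, 2, colSums(frac + pc), "/")
    }
    if (any(apply(log(frac), 1, stats::var) == 0)) {
      stop("zero-variance feature")
    }
    rho <- .sparcc_one(frac, config$n_exclusion_iterations,
                       config$exclusion_threshold)
  } else {
    if (any(apply(x, 1, stats::var) == 0)) stop("zero-variance feature")
    draws <- with_substream(config$seed, 17L, {
      lapply(seq_len(config$n_dirichlet_draws), function(b) {
        g <- matrix(stats::rgamma(length(x), shape = x + 1), nrow(x))
        frac <- sweep(g, 2, colSums(g), "/")
        .sparcc_one(frac, config$n_exclusion_iterations,
                    config$exclusion_threshold)
      })
    })
    rho <- apply(simplify2array(draws), c(1, 2), stats::median)
  }
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each permutation shuffles every feature's values across samples
#' independently (destroying co-variation but keeping margins), recomputes
#' the SparCC matrix, and counts permuted correlations at least as extreme
#' in magnitude as the observed one:
#' \eqn{p_{ij} = (\#\{|\rho^*| \ge |\rho|\} + 1)/(n_{perm} + 1)}. The
#' add-one correction keeps p strictly positive, as BH adjustment requires.
#'
#' @param x the feature-by-sample matrix passed to [sparccCorrelation()].
#' @param observed_rho the observed basis correlation matrix.
#' @param config a [sparccConfig()]; permutations reuse its estimation
#'   settings and seed.
#' @return matrix of two-sided pseudo p-values (diagonal `NA`).
#' @export
sparccPseudoP <- function(x, observed_rho, config = sparccConfig()) {
  x <- as.matrix(x)
  if (!all(dim(observed_rho) == nrow(x))) {
    stop("observed_rho does not match the feature count")
  }
  n <- ncol(x)
  count <- matrix(0, nrow(x), nrow(x))
  with_substream(config$seed, 19L, {
    for (b in seq_len(config$n_permutations)) {
      xp <- t(apply(x, 1, sample))
      rp <- sparccCorrelation(xp, sparccConfig(
        n_exclusion_iterations = config$n_exclusion_iterations,
        exclusion_threshold = config$exclusion_threshold,
        n_dirichlet_draws = config$n_dirichlet_draws,
        n_permutations = 1,
        seed = sample.int(2^30, 1)
      ))
      count <- count + (abs(rp) >= abs(observed_rho))
    }
  })
  p <- (count + 1) / (config$n_permutations + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_rho)
  p
}

#' Threshold a correlation matrix into a signed co-occurrence network
#'
#' BH-adjusts the upper-triangle pseudo p-values, then keeps edges with
#' correlation strictly above `pos_min` or strictly below `neg_max` and
#' adjusted p strictly below `q_max` (positive r = 0.5 exactly is dropped).
#'
#' @param rho basis correlation matrix.
#' @param p matching pseudo p-value matrix.
#' @param pos_min,neg_max,q_max edge filters (defaults 0.5, -0.5, 0.01).
#' @return data.frame of edges: feature_i, feature_j (i < j), rho, p, q,
#'   sign.
#' @export
buildNetwork <- function(rho, p, pos_min = 0.5, neg_max = -0.5,
                         q_max = 0.01) {
  stopifnot(all(dim(rho) == dim(p)))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  q <- bhAdjust(p[upper.tri(p)])
  r <- rho[upper.tri(rho)]
  keep <- (r > pos_min | r < neg_max) & q < q_max
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(rho)))
  out <- data.frame(
    feature_i = ids[ut[keep, 1]],
    feature_j = ids[ut[keep, 2]],
    rho = r[keep],
    p = p[upper.tri(p)][keep],
    q = q[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative")
  )
  out[order(-abs(out$rho)), , drop = FALSE]
}

#' Write an edge list as GraphML
#'
#' @param edges data.frame from [buildNetwork()].
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    edges[, c("feature_i", "feature_j", "rho", "q", "sign")],
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
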