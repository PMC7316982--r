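#' Spearman rank correlation
#'
#' Midranks for ties; rho is the Pearson correlation of the ranks. The
#' p-value uses the exact permutation distribution for n <= 9 without ties
#' (via [stats::cor.test]) and otherwise the t approximation with n - 2
#' degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `rho` and `p`; zero-variance input yields `rho = NA`
#'   with a warning.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 9 && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Correlation-distance hierarchical clustering
#'
#' Agglomerative clustering of the rows of a matrix on
#' \eqn{d = 1 - r_{Pearson}}. Rows with zero variance have undefined
#' correlation; their distances are set to 1 with a warning.
#'
#' @param m numeric matrix, >= 2 rows.
#' @param linkage agglomeration method (default `"average"`; `"ward.D2"`,
#'   `"single"`, `"complete"` etc. as in [stats::hclust]).
#' @return the [stats::hclust] tree (leaf order in `$order`).
#' @export
hierarchicalCluster <- function(m, linkage = "average") {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows")
  constant <- apply(m, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(m)))
  if (any(constant)) {
    warning("constant rows: correlation undefined, distance set to 1")
    r[constant, ] <- 0
    r[, constant] <- 0
    diag(r) <- 1
  }
  stats::hclust(stats::as.dist(1 - r), method = linkage)
}

#' Species-metabolite Spearman association heatmap
#'
#' All pairwise Spearman correlations between species relative abundances
#' and metabolite concentrations over the shared samples, BH-adjusted
#' across the whole grid. Cells with `|rho| < r_mask` are masked from
#' display (strictly below: `|rho| = r_mask` is shown); the two
#' significance marks annotate adjusted p below the looser (`"+"`) and
#' stricter (`"*"`) levels. Rows and columns are ordered by
#' correlation-distance hierarchical clustering of the rho matrix.
#'
#' @param species a species-level [AbundanceTable-class] or matrix.
#' @param metabolites a metabolite-by-sample matrix (e.g. the
#'   `concentrations` element of [simulateMetabolites()]).
#' @param r_mask display threshold on `|rho|` (default 0.4).
#' @param alpha_marks two significance levels, looser first (default
#'   0.05, 0.01).
#' @param use_raw_p mark on raw rather than BH-adjusted p-values.
#' @param linkage clustering linkage (default `"average"`).
#' @return a [CorrelationHeatmap-class].
#' @export
correlationHeatmap <- function(species, metabolites, r_mask = 0.4,
                               alpha_marks = c(0.05, 0.01),
                               use_raw_p = FALSE, linkage = "average") {
  sm <- if (is(species, "AbundanceTable")) abundances(species) else
    as.matrix(species)
  mm <- as.matrix(metabolites)
  shared <- intersect(colnames(sm), colnames(mm))
  if (!length(shared)) stop("no shared samples")
  sm <- sm[, shared, drop = FALSE]
  mm <- mm[, shared, drop = FALSE]
  ns <- nrow(sm); nm <- nrow(mm)
  rho <- p <- matrix(NA_real_, ns, nm,
                     dimnames = list(rownames(sm), rownames(mm)))
  for (i in seq_len(ns)) {
    for (j in seq_len(nm)) {
      r <- suppressWarnings(spearmanCor(sm[i, ], mm[j, ]))
      rho[i, j] <- r$rho
      p[i, j] <- r$p
    }
  }
  q <- matrix(bhAdjust(as.vector(p)), ns, nm, dimnames = dimnames(p))
  basis <- if (use_raw_p) p else q
  marks <- matrix("", ns, nm, dimnames = dimnames(p))
  marks[basis < alpha_marks[1]] <- "+"
  marks[basis < alpha_marks[2]] <- "*"
  mask <- abs(rho) >= r_mask      # TRUE = shown; strict "<" hides
  mask[is.na(mask)] <- FALSE
  row_order <- if (ns > 1) hierarchicalCluster(rho, linkage)$order else 1L
  col_order <- if (nm > 1) hierarchicalCluster(t(rho), linkage)$order else 1L
  new("CorrelationHeatmap", rho = rho, p = p, q = q, mask = mask,
      marks = marks, rowOrder = as.integer(row_order),
      colOrder = as.integer(col_order))
}
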