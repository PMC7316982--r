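#' @importFrom withr with_seed
NULL

# Run `code` under a deterministic RNG substream derived from a global seed.
# Offsets keep the per-stage streams independent while the whole run stays
# reproducible from a single integer; the caller's RNG state is restored.
with_substream <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  sub <- (as.double(seed) * 48271 + as.double(offset) * 9973) %% 2147483587
  withr::with_seed(as.integer(sub) + 1L, code)
}

# stratified fold assignment: every fold contains both classes
stratified_folds <- function(labels, n_folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < n_folds) {
      stop("n_folds exceeds the size of class '", lv, "'")
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

assert_probability <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must lie in [0, 1]")
  }
  invisible(p)
}

#' Write a numeric matrix as a feature-by-sample TSV
#'
#' First column holds feature identifiers, remaining columns one sample each;
#' the flat-file handoff format used between pipeline stages.
#'
#' @param m numeric matrix with row and column names.
#' @param path output file path.
#' @param id_name header for the identifier column.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path, id_name = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV into a matrix
#'
#' @param path TSV with the feature identifier in the first column.
#' @return numeric matrix, features in rows.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
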