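#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.ABUNDANCE_LEVELS <- c("gene", "genus", "species", "MLG", "metabolite")
# levels whose per-sample profiles are closed to 1 (relative abundances)
.COMPOSITIONAL_LEVELS <- c("genus", "species")

#' AbundanceTable: feature-by-sample abundances with group labels
#'
#' The lingua franca of the pipeline: a [SummarizedExperiment] whose single
#' `"abundance"` assay holds nonnegative feature-by-sample values, whose
#' `colData$group` carries the case/control label, and whose metadata records
#' the feature level (gene, genus, species, MLG, or metabolite). Taxon-level
#' tables (genus, species) are compositional: each sample column sums to one.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  lv <- metadata(object)$level
  if (is.null(lv) || !lv %in% .ABUNDANCE_LEVELS) {
    msg <- c(msg, paste("metadata 'level' must be one of:",
                        paste(.ABUNDANCE_LEVELS, collapse = ", ")))
  }
  if (!"abundance" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'abundance' is required")
  } else {
    v <- assay(object, "abundance")
    if (any(v < 0)) msg <- c(msg, "abundances must be nonnegative")
    if (!is.null(lv) && lv %in% .COMPOSITIONAL_LEVELS && ncol(v) > 0) {
      cs <- colSums(v)
      if (any(abs(cs - 1) > 1e-9)) {
        msg <- c(msg, "compositional table: sample columns must sum to 1")
      }
    }
    if (anyDuplicated(rownames(v))) msg <- c(msg, "feature ids must be unique")
  }
  if (!"group" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(colData(object)$group %in% c("case", "control"))) {
    msg <- c(msg, "group labels must be 'case' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values nonnegative feature-by-sample matrix with dimnames.
#' @param group character vector of `"case"`/`"control"`, one per sample.
#' @param level feature level: `"gene"`, `"genus"`, `"species"`, `"MLG"`, or
#'   `"metabolite"`. Taxon levels are validated as compositional.
#' @param ... further columns for `colData` (e.g. cohort, age, sex).
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(.6, .4, .3, .7), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
#' at <- AbundanceTable(m, group = c("case", "control"), level = "species")
#' @export
AbundanceTable <- function(values, group, level = "species", ...) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(group = group, ..., row.names = colnames(values)),
    metadata = list(level = level)
  )
  new("AbundanceTable", se)
}

#' @describeIn AbundanceTable abundance matrix accessor
#' @param x an `AbundanceTable`.
#' @export
abundances <- function(x) assay(x, "abundance")

#' @describeIn AbundanceTable case/control labels accessor
#' @export
groupLabels <- function(x) as.character(colData(x)$group)

#' @describeIn AbundanceTable feature level accessor
#' @export
featureLevel <- function(x) metadata(x)$level

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable (", featureLevel(object), " level): ",
      nrow(object), " features x ", ncol(object), " samples; ",
      sum(groupLabels(object) == "case"), " case / ",
      sum(groupLabels(object) == "control"), " control\n", sep = "")
})

#' GeneCatalog: per-gene lengths and length-normalised depths
#'
#' Holds the gene-by-sample length-normalised abundance (depth) matrix, the
#' gene lengths in bp, the per-gene taxonomic annotation used for MLG
#' taxonomy voting, and (for synthetic catalogs) the planted cluster truth.
#'
#' @slot depth gene-by-sample nonnegative matrix.
#' @slot geneLength integer bp per gene (>= 100).
#' @slot annotation data.frame with columns gene_id, species_hit, genus_hit,
#'   dna_identity, protein_identity, query_overlap.
#' @slot trueCluster planted cluster id per gene (`NA` outside simulations).
#' @export
setClass("GeneCatalog", representation(
  depth = "matrix",
  geneLength = "numeric",
  annotation = "data.frame",
  trueCluster = "character"
))

setValidity("GeneCatalog", function(object) {
  msg <- character()
  if (any(object@depth < 0)) msg <- c(msg, "depths must be nonnegative")
  if (length(object@geneLength) != nrow(object@depth)) {
    msg <- c(msg, "one length per gene required")
  }
  if (any(object@geneLength < 100)) msg <- c(msg, "gene lengths must be >= 100 bp")
  if (length(object@trueCluster) &&
      length(object@trueCluster) != nrow(object@depth)) {
    msg <- c(msg, "trueCluster must match the gene count")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCatalog
#' @param depth gene-by-sample nonnegative matrix with gene ids as rownames.
#' @param geneLength gene lengths, bp.
#' @param annotation per-gene taxonomic hit table (may be empty).
#' @param trueCluster optional planted cluster labels (synthetic data only).
#' @return a [GeneCatalog-class] object.
#' @export
GeneCatalog <- function(depth, geneLength, annotation = data.frame(),
                        trueCluster = character()) {
  new("GeneCatalog", depth = as.matrix(depth),
      geneLength = as.numeric(geneLength),
      annotation = annotation, trueCluster = as.character(trueCluster))
}

#' @describeIn GeneCatalog depth matrix accessor
#' @param x a `GeneCatalog`.
#' @export
geneDepth <- function(x) x@depth

#' @describeIn GeneCatalog gene length accessor
#' @export
geneLengths <- function(x) stats::setNames(x@geneLength, rownames(x@depth))

#' @describeIn GeneCatalog annotation accessor
#' @export
geneAnnotation <- function(x) x@annotation

#' @describeIn GeneCatalog planted cluster truth accessor
#' @export
trueClusters <- function(x) {
  if (length(x@trueCluster)) stats::setNames(x@trueCluster, rownames(x@depth))
  else NULL
}

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog: ", nrow(object@depth), " genes x ",
      ncol(object@depth), " samples; ",
      nrow(object@annotation), " annotated hits\n", sep = "")
})

#' MLGSet: metagenomic linkage groups
#'
#' A set of co-abundance gene clusters (each with more than 50 member genes),
#' their length-weighted abundance profiles, and their voted taxonomy.
#'
#' @slot members named list: MLG id -> character vector of member gene ids.
#' @slot abundance MLG-by-sample matrix of length-weighted mean depths.
#' @slot taxonomy data.frame with columns mlg_id, level (species, genus or
#'   unclassified), name, fraction (the winning vote fraction).
#' @export
setClass("MLGSet", representation(
  members = "list",
  abundance = "matrix",
  taxonomy = "data.frame"
))

setValidity("MLGSet", function(object) {
  msg <- character()
  if (length(object@members) &&
      any(duplicated(unlist(object@members, use.names = FALSE)))) {
    msg <- c(msg, "a gene may belong to at most one MLG")
  }
  if (nrow(object@abundance) && any(object@abundance < 0)) {
    msg <- c(msg, "MLG abundances must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MLGSet member gene ids accessor
#' @param x an `MLGSet`.
#' @export
mlgMembers <- function(x) x@members

#' @describeIn MLGSet MLG-by-sample abundance accessor
#' @export
mlgAbundances <- function(x) x@abundance

#' @describeIn MLGSet voted taxonomy accessor
#' @export
mlgTaxonomy <- function(x) x@taxonomy

setMethod("show", "MLGSet", function(object) {
  sizes <- lengths(object@members)
  cat("MLGSet: ", length(object@members), " linkage groups",
      if (length(sizes)) paste0(" (", min(sizes), "-", max(sizes), " genes)"),
      "\n", sep = "")
  if (nrow(object@taxonomy)) {
    tab <- table(object@taxonomy$level)
    cat("  taxonomy: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
})

#' StabilityResult: Monte-Carlo PLS-DA coefficient stability
#'
#' Per-variable regression coefficients over Monte-Carlo resamples, their
#' means and spreads, the stability statistic c_j = mean/sd, and the
#' cross-validation-selected variable set.
#'
#' @slot betaResamples N-by-p matrix of per-resample PLS coefficients.
#' @slot betaMean,betaSd,c per-variable summaries (`c` is `NA` where the
#'   coefficient spread is exactly zero).
#' @slot selected selected variable names (empty before the cutoff scan).
#' @slot accuracyByCutoff data.frame(cutoff, accuracy, n_vars).
#' @slot importance `|c_j|` of the selected variables.
#' @export
setClass("StabilityResult", representation(
  betaResamples = "matrix",
  betaMean = "numeric",
  betaSd = "numeric",
  c = "numeric",
  selected = "character",
  accuracyByCutoff = "data.frame",
  importance = "numeric"
))

setValidity("StabilityResult", function(object) {
  ok <- is.finite(object@betaSd) & object@betaSd > 0
  bad <- ok & abs(object@c - object@betaMean / object@betaSd) > 1e-8
  if (any(bad, na.rm = TRUE)) "c must equal betaMean/betaSd where betaSd > 0"
  else TRUE
})

#' @describeIn StabilityResult stability statistics c_j accessor
#' @param x a `StabilityResult`.
#' @export
stabilityC <- function(x) x@c

#' @describeIn StabilityResult selected variable names accessor
#' @export
selectedVariables <- function(x) x@selected

#' @describeIn StabilityResult accuracy-vs-cutoff curve accessor
#' @export
accuracyByCutoff <- function(x) x@accuracyByCutoff

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult: ", ncol(object@betaResamples), " variables, ",
      nrow(object@betaResamples), " resamples; ",
      length(object@selected), " selected\n", sep = "")
})

#' CorrelationHeatmap: species-metabolite Spearman association grid
#'
#' @slot rho,p,q species-by-metabolite matrices (q is BH-adjusted over the
#'   whole grid).
#' @slot mask logical; `TRUE` where the pair is shown (|rho| >= the display
#'   threshold).
#' @slot marks character: `"*"` below the stricter significance level,
#'   `"+"` below the looser one, `""` otherwise.
#' @slot rowOrder,colOrder permutations from correlation-distance
#'   hierarchical clustering.
#' @export
setClass("CorrelationHeatmap", representation(
  rho = "matrix", p = "matrix", q = "matrix",
  mask = "matrix", marks = "matrix",
  rowOrder = "integer", colOrder = "integer"
))

setValidity("CorrelationHeatmap", function(object) {
  msg <- character()
  if (any(abs(object@rho) > 1 + 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "rho must lie in [-1, 1]")
  }
  if (!identical(sort(object@rowOrder), seq_len(nrow(object@rho))) ||
      !identical(sort(object@colOrder), seq_len(ncol(object@rho)))) {
    msg <- c(msg, "orders must be permutations")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationHeatmap", function(object) {
  cat("CorrelationHeatmap: ", nrow(object@rho), " species x ",
      ncol(object@rho), " metabolites; ",
      sum(object@mask, na.rm = TRUE), " shown pairs\n", sep = "")
})
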