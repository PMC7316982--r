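#' Cluster marker genes into metagenomic linkage groups
#'
#' Canopy-style co-abundance clustering on log-transformed depths (the CAG
#' lineage). Genes are visited in their input order; each unassigned gene
#' seeds a canopy whose running centroid absorbs unassigned genes with
#' Pearson correlation at or above `corr_threshold`, recomputing the
#' centroid until membership stabilises. Canopies whose centroids correlate
#' at or above the threshold are then merged. Only clusters with more than
#' 50 member genes (size >= `min_size`) are reported as MLGs, ordered by
#' size. The log transform uses a pseudocount of half the smallest nonzero
#' depth, which avoids minus infinity while preserving rank structure.
#'
#' @param catalog a [GeneCatalog-class].
#' @param marker_ids gene ids to cluster (e.g. the q < 0.05 marker genes);
#'   must be a subset of the catalog.
#' @param corr_threshold Pearson correlation for canopy membership and
#'   merging, in (0, 1); default 0.9.
#' @param min_size minimum cluster size kept (default 51, i.e. > 50 genes).
#' @return an [MLGSet-class] (taxonomy empty; see [assignTaxonomy()]),
#'   with abundance profiles from [mlgAbundance()]. Fewer than `min_size`
#'   markers yield an empty set, not an error.
#' @export
clusterMarkerGenes <- function(catalog, marker_ids, corr_threshold = 0.9,
                               min_size = 51) {
  stopifnot(is(catalog, "GeneCatalog"))
  if (corr_threshold <= 0 || corr_threshold >= 1) {
    stop("corr_threshold must lie in (0, 1)")
  }
  depth <- geneDepth(catalog)
  missing <- setdiff(marker_ids, rownames(depth))
  if (length(missing)) stop("marker ids absent from catalog: ", missing[1])
  empty <- new("MLGSet", members = list(),
               abundance = matrix(0, 0, ncol(depth),
                                  dimnames = list(NULL, colnames(depth))),
               taxonomy = data.frame())
  if (length(marker_ids) < min_size) return(empty)

  d <- depth[marker_ids, , drop = FALSE]
  pc <- min(d[d > 0]) / 2
  L <- log(d + pc)
  # row-standardise once so correlations against a centroid are crossprods
  Ls <- L - rowMeans(L)
  sds <- sqrt(rowSums(Ls^2))
  sds[sds == 0] <- 1      # constant genes correlate with nothing
  Ls <- Ls / sds

  n_mark <- nrow(Ls)
  assigned <- rep(NA_integer_, n_mark)
  centroids <- list()
  k <- 0L
  cor_to <- function(centroid) {
    cz <- centroid - mean(centroid)
    s <- sqrt(sum(cz^2))
    if (s == 0) return(rep(0, n_mark))
    as.vector(Ls %*% (cz / s))
  }
  for (g in seq_len(n_mark)) {
    if (!is.na(assigned[g])) next
    k <- k + 1L
    members <- g
    centroid <- L[g, ]
    repeat {
      cand <- which(is.na(assigned) | assigned == k)
      rho <- cor_to(centroid)
      new_members <- cand[rho[cand] >= corr_threshold]
      new_members <- sort(union(new_members, g))  # seed always stays
      if (identical(new_members, members)) break
      members <- new_members
      centroid <- colMeans(L[members, , drop = FALSE])
    }
    assigned[assigned == k] <- NA_integer_
    assigned[members] <- k
    centroids[[k]] <- centroid
  }
  # merge canopies whose centroids still correlate above threshold
  active <- seq_len(k)
  repeat {
    if (length(active) < 2) break
    C <- do.call(rbind, centroids[active])
    rho <- suppressWarnings(stats::cor(t(C)))
    rho[!is.finite(rho)] <- 0
    diag(rho) <- -Inf
    best <- which(rho == max(rho), arr.ind = TRUE)[1, ]
    if (rho[best[1], best[2]] < corr_threshold) break
    a <- active[min(best)]; b <- active[max(best)]
    assigned[assigned == b] <- a
    centroids[[a]] <- colMeans(L[assigned == a, , drop = FALSE])
    active <- setdiff(active, b)
  }
  sizes <- table(assigned)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(keep)) return(empty)
  keep <- keep[order(-sizes[as.character(keep)], keep)]
  members <- lapply(keep, function(cl) marker_ids[which(assigned == cl)])
  names(members) <- sprintf("MLG_%03d", seq_along(members))
  ab <- do.call(rbind, lapply(members, mlgAbundance, catalog = catalog))
  rownames(ab) <- names(members)
  new("MLGSet", members = members, abundance = ab, taxonomy = data.frame())
}

#' Length-weighted MLG abundance
#'
#' The per-sample abundance of a linkage group is the gene-length-weighted
#' mean of its members' length-normalised depths:
#' \eqn{a_s = \sum_g L_g a_{gs} / \sum_g L_g}. Linear in the member
#' abundances.
#'
#' @param members member gene ids (nonempty, all present in the catalog).
#' @param catalog a [GeneCatalog-class].
#' @return named per-sample abundance vector.
#' @export
mlgAbundance <- function(members, catalog) {
  stopifnot(is(catalog, "GeneCatalog"))
  if (!length(members)) stop("empty member set")
  depth <- geneDepth(catalog)
  if (!all(members %in% rownames(depth))) {
    stop("member genes absent from catalog")
  }
  w <- geneLengths(catalog)[members]
  colSums(depth[members, , drop = FALSE] * w) / sum(w)
}

#' Vote-based MLG taxonomy assignment
#'
#' Species assignment requires at least 90% of the member genes to hit one
#' species with DNA identity >= 95% and query overlap >= 70%. Failing that,
#' genus assignment requires at least 80% of the members to hit one genus
#' with both DNA and protein identity >= 85%. Otherwise the MLG is
#' unclassified. All thresholds are inclusive; ties break by the higher
#' qualifying fraction, then lexicographic name. Genes without annotation
#' simply never qualify.
#'
#' @param members member gene ids of one MLG.
#' @param annotation data.frame with columns gene_id, species_hit,
#'   genus_hit, dna_identity, protein_identity, query_overlap.
#' @return list with `level` (`"species"`, `"genus"`, or
#'   `"unclassified"`), `name` (`NA` when unclassified), and `fraction`
#'   (the winning vote fraction).
#' @export
assignTaxonomy <- function(members, annotation) {
  n <- length(members)
  if (!n) stop("empty member set")
  ann <- annotation[annotation$gene_id %in% members, , drop = FALSE]
  vote <- function(hits) {
    if (!nrow(hits)) return(NULL)
    frac <- sort(table(hits$name) / n, decreasing = TRUE)
    # table sorts names lexicographically within equal counts already;
    # re-sort explicitly for the documented tie-break
    ord <- order(-frac, names(frac))
    list(name = names(frac)[ord][1], fraction = as.numeric(frac[ord][1]))
  }
  sp <- ann[!is.na(ann$species_hit) & ann$dna_identity >= 95 &
              ann$query_overlap >= 0.70, , drop = FALSE]
  if (nrow(sp)) {
    best <- vote(data.frame(name = sp$species_hit))
    if (!is.null(best) && best$fraction >= 0.90) {
      return(list(level = "species", name = best$name,
                  fraction = best$fraction))
    }
  }
  gn <- ann[!is.na(ann$genus_hit) & ann$dna_identity >= 85 &
              ann$protein_identity >= 85, , drop = FALSE]
  if (nrow(gn)) {
    best <- vote(data.frame(name = gn$genus_hit))
    if (!is.null(best) && best$fraction >= 0.80) {
      return(list(level = "genus", name = best$name,
                  fraction = best$fraction))
    }
  }
  list(level = "unclassified", name = NA_character_, fraction = 0)
}

#' Assign taxonomy to every MLG in a set
#'
#' @param mlgs an [MLGSet-class].
#' @param annotation per-gene annotation table (see [assignTaxonomy()]).
#' @return the `MLGSet` with its taxonomy slot filled.
#' @export
assignTaxonomySet <- function(mlgs, annotation) {
  stopifnot(is(mlgs, "MLGSet"))
  tx <- lapply(mlgMembers(mlgs), assignTaxonomy, annotation = annotation)
  mlgs@taxonomy <- data.frame(
    mlg_id = names(tx),
    level = vapply(tx, `[[`, character(1), "level"),
    name = vapply(tx, `[[`, character(1), "name"),
    fraction = vapply(tx, `[[`, numeric(1), "fraction"),
    row.names = NULL
  )
  validObject(mlgs)
  mlgs
}
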