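#' Cohort design for the synthetic generator
#'
#' Bundles every knob of the synthetic two-group metagenomic cohort. The
#' defaults emulate the discovery-phase design the pipeline targets: 100
#' cases and 100 controls, heavy-tailed (log-normal) abundances, planted
#' co-abundant gene clusters with taxonomic labels, planted differential
#' taxa at a two-fold-per-log2-unit effect, and metabolites driven by
#' specific species.
#'
#' @param n_per_group samples per arm (default 100, the discovery cohort).
#' @param n_genes total genes in the catalog.
#' @param n_clusters planted co-abundance clusters.
#' @param cluster_size_range inclusive (min, max) genes per cluster.
#' @param frac_differential_clusters fraction of gene clusters given a
#'   case/control shift.
#' @param frac_differential_taxa fraction of taxa shifted in taxon tables
#'   (default 0.05: differential species are a small minority of the
#'   community, so closure leaves their fold change visible).
#' @param effect_log2fc log2 fold change of differential features.
#' @param noise_sd log-scale within-cluster gene noise (sd of the gene-level
#'   deviation around the cluster base trajectory).
#' @param annotated_fraction fraction of each cluster's genes annotated to
#'   the cluster's true species above the species-vote thresholds.
#' @param n_species,n_metabolites taxon and metabolite panel sizes.
#' @param target_rho intended species-metabolite Spearman correlation for
#'   linked pairs (0 plants no links).
#' @param seed integer master seed; every generator draws from substreams of
#'   it, so identical (design, seed) pairs are bit-reproducible.
#' @return a `CohortDesign` list.
#' @examples
#' d <- cohortDesign(n_per_group = 20, n_genes = 200, n_clusters = 2)
#' @export
cohortDesign <- function(n_per_group = 100, n_genes = 5000, n_clusters = 10,
                         cluster_size_range = c(55, 120),
                         frac_differential_clusters = 0.5,
                         frac_differential_taxa = 0.05,
                         effect_log2fc = 2, noise_sd = 0.3,
                         annotated_fraction = 0.95,
                         n_species = 100, n_metabolites = 20,
                         target_rho = 0.8, seed = 1L) {
  d <- list(n_per_group = n_per_group, n_genes = n_genes,
            n_clusters = n_clusters, cluster_size_range = cluster_size_range,
            frac_differential_clusters = frac_differential_clusters,
            frac_differential_taxa = frac_differential_taxa,
            effect_log2fc = effect_log2fc, noise_sd = noise_sd,
            annotated_fraction = annotated_fraction,
            n_species = n_species, n_metabolites = n_metabolites,
            target_rho = target_rho, seed = as.integer(seed))
  counts <- c("n_per_group", "n_genes", "n_clusters", "n_species",
              "n_metabolites")
  if (any(unlist(d[counts]) < 1)) stop("all counts must be positive")
  fr <- c(d$frac_differential_clusters, d$frac_differential_taxa,
          d$annotated_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(d$target_rho) >= 1) stop("target_rho must lie in (-1, 1)")
  if (d$noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(d, class = "CohortDesign")
}

.sample_names <- function(design) {
  c(sprintf("case_%03d", seq_len(design$n_per_group)),
    sprintf("ctrl_%03d", seq_len(design$n_per_group)))
}

.group_labels <- function(design) {
  rep(c("case", "control"), each = design$n_per_group)
}

#' Simulate a gene catalog with planted co-abundance clusters
#'
#' Each cluster carries one shared log-normal base trajectory across samples;
#' member genes scatter around it with log-scale noise `noise_sd`, so the
#' within-cluster Pearson correlation on log depth is
#' var(base)/(var(base) + noise_sd^2). A subset of clusters shifts its case
#' mean by `effect_log2fc` log2 units. Annotations place `annotated_fraction`
#' of each cluster's genes on the cluster's true species (DNA identity
#' 95-99%, query overlap 0.7-1.0, protein identity 85-99); the remainder get
#' sub-threshold decoy hits. Background genes are mutually uncorrelated.
#'
#' @param design a [cohortDesign()].
#' @return list with `catalog` (a [GeneCatalog-class] including annotation
#'   and planted `trueCluster`) and `truth` (data.frame: cluster_id, species,
#'   genus, differential).
#' @export
simulateGeneCatalog <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  with_substream(design$seed, 11L, {
    n <- 2L * design$n_per_group
    size_choices <- seq(design$cluster_size_range[1],
                        design$cluster_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices),
                                     design$n_clusters, replace = TRUE)]
    if (sum(sizes) > design$n_genes) {
      stop("cluster sizes exceed n_genes; enlarge the catalog")
    }
    n_bg <- design$n_genes - sum(sizes)
    n_diff <- round(design$frac_differential_clusters * design$n_clusters)
    differential <- seq_len(design$n_clusters) <= n_diff
    shift <- design$effect_log2fc * log(2)
    grp_case <- .group_labels(design) == "case"

    gene_ids <- sprintf("gene_%05d", seq_len(design$n_genes))
    depth <- matrix(0, design$n_genes, n,
                    dimnames = list(gene_ids, .sample_names(design)))
    true_cluster <- rep(NA_character_, design$n_genes)
    row <- 1L
    for (k in seq_len(design$n_clusters)) {
      base <- stats::rnorm(n, mean = stats::rnorm(1, 0, 1), sd = 1)
      if (differential[k]) base[grp_case] <- base[grp_case] + shift
      idx <- row:(row + sizes[k] - 1L)
      noise <- matrix(stats::rnorm(sizes[k] * n, 0, design$noise_sd),
                      sizes[k], n)
      depth[idx, ] <- exp(sweep(noise, 2, base, "+"))
      true_cluster[idx] <- sprintf("cluster_%02d", k)
      row <- row + sizes[k]
    }
    if (n_bg > 0) {
      idx <- row:(row + n_bg - 1L)
      depth[idx, ] <- exp(matrix(stats::rnorm(n_bg * n, stats::rnorm(n_bg, 0, 1), 1),
                                 n_bg, n))
    }
    lengths <- sample(100:5000, design$n_genes, replace = TRUE)

    species <- sprintf("Species_%02d", seq_len(design$n_clusters))
    genus <- sprintf("Genus_%02d", seq_len(design$n_clusters))
    ann <- vector("list", design$n_clusters)
    row <- 1L
    for (k in seq_len(design$n_clusters)) {
      idx <- row:(row + sizes[k] - 1L)
      n_good <- round(design$annotated_fraction * sizes[k])
      good <- idx[seq_len(n_good)]
      decoy <- setdiff(idx, good)
      ann[[k]] <- rbind(
        data.frame(gene_id = gene_ids[good], species_hit = species[k],
                   genus_hit = genus[k],
                   dna_identity = stats::runif(n_good, 95, 99),
                   protein_identity = stats::runif(n_good, 85, 99),
                   query_overlap = stats::runif(n_good, 0.7, 1.0)),
        if (length(decoy)) {
          data.frame(gene_id = gene_ids[decoy], species_hit = species[k],
                     genus_hit = genus[k],
                     dna_identity = stats::runif(length(decoy), 80, 94),
                     protein_identity = stats::runif(length(decoy), 60, 84),
                     query_overlap = stats::runif(length(decoy), 0.3, 0.69))
        }
      )
      row <- row + sizes[k]
    }
    annotation <- do.call(rbind, ann)

    catalog <- GeneCatalog(depth, lengths, annotation, true_cluster)
    truth <- data.frame(cluster_id = sprintf("cluster_%02d",
                                             seq_len(design$n_clusters)),
                        species = species, genus = genus,
                        differential = differential)
    list(catalog = catalog, truth = truth)
  })
}

#' Simulate a compositional taxon abundance table
#'
#' Log-normal taxon abundances renormalised per sample to relative
#' abundances; the first `round(frac_differential_taxa * n)` taxa shift
#' their case-group mean by `effect_log2fc` log2 units before closure.
#'
#' @param design a [cohortDesign()].
#' @param level `"species"` or `"genus"`.
#' @return an [AbundanceTable-class] with attribute `"truth"` naming the
#'   planted differential taxa.
#' @export
simulateTaxonTable <- function(design, level = c("species", "genus")) {
  stopifnot(inherits(design, "CohortDesign"))
  level <- match.arg(level)
  if (design$n_species < 2) stop("need at least 2 taxa")
  offset <- if (level == "species") 23L else 29L
  with_substream(design$seed, offset, {
    n <- 2L * design$n_per_group
    p <- design$n_species
    ids <- sprintf("%s_%03d", if (level == "species") "sp" else "gen",
                   seq_len(p))
    n_diff <- round(design$frac_differential_taxa * p)
    diff_idx <- seq_len(n_diff)
    mu <- stats::rnorm(p, 0, 1.5)
    logab <- matrix(stats::rnorm(p * n, mu, 1), p, n,
                    dimnames = list(ids, .sample_names(design)))
    if (n_diff > 0 && design$effect_log2fc != 0) {
      grp_case <- .group_labels(design) == "case"
      logab[diff_idx, grp_case] <-
        logab[diff_idx, grp_case] + design$effect_log2fc * log(2)
    }
    ab <- exp(logab)
    ab <- sweep(ab, 2, colSums(ab), "/")
    tab <- AbundanceTable(ab, .group_labels(design), level = level)
    attr(tab, "truth") <- ids[diff_idx]
    tab
  })
}

#' Simulate a metabolite panel linked to driver species
#'
#' Each linked metabolite is a monotone (exponential) transform of a latent
#' Gaussian correlated with the driver species' log abundance. The latent
#' Pearson correlation is set to `2*sin(pi*target_rho/6)` so the empirical
#' Spearman correlation concentrates on `target_rho`; Spearman's invariance
#' under monotone maps makes the closure and the exponential irrelevant.
#' Unlinked metabolites are independent log-normals. With `target_rho = 0`
#' no links are planted.
#'
#' @param design a [cohortDesign()].
#' @param species a species-level [AbundanceTable-class].
#' @return list with `concentrations` (metabolite-by-sample matrix),
#'   `class` (amino_acid/fatty_acid), and `linked_species` (named character;
#'   `NA` for unlinked metabolites).
#' @export
simulateMetabolites <- function(design, species) {
  stopifnot(inherits(design, "CohortDesign"), is(species, "AbundanceTable"))
  ab <- abundances(species)
  if (nrow(ab) < 1) stop("species table must contain at least one taxon")
  if (abs(design$target_rho) >= 1) stop("target_rho must lie in (-1, 1)")
  with_substream(design$seed, 37L, {
    n <- ncol(ab)
    m <- design$n_metabolites
    ids <- sprintf("met_%02d", seq_len(m))
    n_linked <- if (design$target_rho == 0) 0L else min(m %/% 2L, nrow(ab))
    r_latent <- 2 * sin(pi * design$target_rho / 6)
    conc <- matrix(NA_real_, m, n, dimnames = list(ids, colnames(ab)))
    linked <- stats::setNames(rep(NA_character_, m), ids)
    for (j in seq_len(m)) {
      if (j <= n_linked) {
        driver <- rownames(ab)[j]
        # normal scores of the driver's abundance ranks: a monotone map of
        # the species profile with an exactly Gaussian margin
        u <- stats::qnorm(rank(ab[driver, ], ties.method = "average") /
                            (n + 1))
        z <- r_latent * u + sqrt(1 - r_latent^2) * stats::rnorm(n)
        linked[j] <- driver
      } else {
        z <- stats::rnorm(n)
      }
      conc[j, ] <- exp(z + stats::rnorm(1, 2, 0.5))
    }
    list(concentrations = conc,
         class = rep(c("amino_acid", "fatty_acid"), length.out = m),
         linked_species = linked)
  })
}

#' Simulate a multi-arm mouse aneurysm experiment
#'
#' Per animal: Bernoulli aneurysm with the arm's incidence probability;
#' among aneurysm-positive animals, Bernoulli rupture with the arm's
#' conditional rupture probability; ruptured (symptomatic) animals get a
#' symptom-onset day from a geometric distribution truncated to days 1-21,
#' all other animals are censored at day 21.
#'
#' @param arms data.frame with columns `label`, `n`, `p_aneurysm`,
#'   `p_rupture` (conditional on aneurysm).
#' @param seed integer seed.
#' @param onset_p daily event probability of the truncated geometric.
#' @return data.frame: mouse_id, arm, aneurysm, rupture, onset_day, censored.
#' @examples
#' arms <- data.frame(label = c("UIA-FMT", "Con-FMT"), n = 20,
#'                    p_aneurysm = c(0.85, 0.45), p_rupture = c(0.82, 0.22))
#' simulateMouseExperiment(arms, seed = 1)
#' @export
simulateMouseExperiment <- function(arms, seed = 1L, onset_p = 0.15) {
  stopifnot(all(c("label", "n", "p_aneurysm", "p_rupture") %in% names(arms)))
  if (any(arms$n < 1)) stop("each arm needs at least one animal")
  assert_probability(c(arms$p_aneurysm, arms$p_rupture), "arm probabilities")
  with_substream(seed, 41L, {
    out <- lapply(seq_len(nrow(arms)), function(i) {
      n <- arms$n[i]
      aneurysm <- stats::runif(n) < arms$p_aneurysm[i]
      rupture <- aneurysm & (stats::runif(n) < arms$p_rupture[i])
      # truncated geometric on 1..21 via inverse CDF
      u <- stats::runif(n)
      day <- 1 + floor(log(1 - u * (1 - (1 - onset_p)^21)) / log(1 - onset_p))
      onset <- ifelse(rupture, pmin(day, 21), 21L)
      data.frame(mouse_id = sprintf("%s_m%02d", arms$label[i], seq_len(n)),
                 arm = arms$label[i], aneurysm = aneurysm, rupture = rupture,
                 onset_day = as.integer(onset), censored = !rupture)
    })
    do.call(rbind, out)
  })
}

#' Write the synthetic cohort to TSV files
#'
#' Flat-file handoff: feature-by-sample tables with the feature id in the
#' first column, plus metadata, annotation, and planted-truth tables.
#'
#' @param design a [cohortDesign()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
writeSyntheticCohort <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gc <- simulateGeneCatalog(design)
  sp <- simulateTaxonTable(design, "species")
  met <- simulateMetabolites(design, sp)
  paths <- c(
    gene_depth = file.path(dir, "gene_depth.tsv"),
    gene_meta = file.path(dir, "gene_meta.tsv"),
    annotation = file.path(dir, "gene_annotation.tsv"),
    species = file.path(dir, "species_abundance.tsv"),
    metabolites = file.path(dir, "metabolite_concentrations.tsv"),
    metadata = file.path(dir, "sample_metadata.tsv"),
    truth = file.path(dir, "planted_truth.tsv")
  )
  writeMatrixTSV(geneDepth(gc$catalog), paths["gene_depth"], "gene_id")
  utils::write.table(
    data.frame(gene_id = rownames(geneDepth(gc$catalog)),
               length_bp = geneLengths(gc$catalog)),
    paths["gene_meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(geneAnnotation(gc$catalog), paths["annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeMatrixTSV(abundances(sp), paths["species"], "species_id")
  writeMatrixTSV(met$concentrations, paths["metabolites"], "metabolite_id")
  utils::write.table(
    data.frame(sample_id = colnames(abundances(sp)),
               group = groupLabels(sp)),
    paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    kind = c(rep("differential_taxon", length(attr(sp, "truth"))),
             rep("gene_cluster", nrow(gc$truth))),
    id = c(attr(sp, "truth"), gc$truth$cluster_id),
    detail = c(rep("", length(attr(sp, "truth"))),
               paste0(gc$truth$species, ";differential=",
                      gc$truth$differential)))
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
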