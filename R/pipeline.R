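#' Default pipeline configuration
#'
#' A demonstration-scale configuration for [runPipeline()]: a synthetic
#' cohort small enough for an interactive end-to-end run, every stage
#' enabled, and per-stage parameters at their documented defaults.
#'
#' @param outdir output directory.
#' @param seed master seed propagated to every stochastic stage.
#' @return a `RunConfig` list with elements `design` (a [cohortDesign()]),
#'   `stages` (named logical), per-stage parameter lists, `outdir`, `seed`.
#' @export
pipelineConfig <- function(outdir = tempfile("mwas_run_"), seed = 1L) {
  list(
    design = cohortDesign(n_per_group = 40, n_genes = 400, n_clusters = 3,
                          cluster_size_range = c(55, 70),
                          frac_differential_clusters = 0.67,
                          effect_log2fc = 2, noise_sd = 0.3,
                          n_species = 40, n_metabolites = 10,
                          target_rho = 0.8, seed = seed),
    stages = c(simulate = TRUE, diversity = TRUE, diffabund = TRUE,
               mlg = TRUE, network = TRUE, select = TRUE, classify = TRUE,
               correlate = TRUE, preclinical = TRUE),
    diffabund = list(alpha_q = 0.05),
    network = list(n_permutations = 40, n_dirichlet_draws = 5),
    select = list(N = 200, cutoff_grid = seq(0.5, 3, 0.5)),
    classify = list(n_folds = 4, n_trials = 5),
    preclinical = list(arms = data.frame(
      label = c("UIA-FMT", "Con-FMT"), n = 20,
      p_aneurysm = c(0.85, 0.45), p_rupture = c(0.82, 0.22))),
    outdir = outdir,
    seed = as.integer(seed)
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order (simulate, diversity,
#' differential abundance, MLG construction, SparCC network, stability
#' selection, classifier evaluation, metabolite correlation, preclinical
#' statistics), writing each stage's outputs as flat files before the next
#' starts, and returns a machine-readable run report with headline
#' statistics. Outputs are pure functions of (config, seed).
#'
#' @param config a [pipelineConfig()]-shaped list.
#' @return the run report (also written as `run_report.json`): per-stage
#'   status, headline statistics, output manifest, and the seed.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  report <- list(package_version = as.character(utils::packageVersion("mwaskit")),
                 seed = config$seed, stages = list(), headline = list(),
                 manifest = character())
  add_file <- function(p) report$manifest <<- c(report$manifest, unname(p))
  mark <- function(stage, params = list()) {
    report$stages[[stage]] <<- list(status = "ok", parameters = params)
  }

  design <- config$design
  species <- NULL; catalog <- NULL; mlgs <- NULL; met <- NULL

  if (stages["simulate"]) {
    paths <- writeSyntheticCohort(design, file.path(config$outdir, "synthetic"))
    add_file(paths)
    gc <- simulateGeneCatalog(design)
    catalog <- gc$catalog
    species <- simulateTaxonTable(design, "species")
    met <- simulateMetabolites(design, species)
    mark("simulate", design[setdiff(names(design), "seed")])
  }

  if (stages["diversity"] && !is.null(species)) {
    ab <- abundances(species)
    shannon <- apply(ab, 2, shannonIndex)
    d <- brayCurtis(species)
    ord <- pcoa(d)
    an <- anosim(d, groupLabels(species), seed = config$seed)
    f <- file.path(config$outdir, "bray_curtis.tsv")
    writeMatrixTSV(d, f, "sample_id"); add_file(f)
    f <- file.path(config$outdir, "pcoa_coordinates.tsv")
    writeMatrixTSV(ord$coordinates, f, "sample_id"); add_file(f)
    report$headline$shannon_mean_case <-
      mean(shannon[groupLabels(species) == "case"])
    report$headline$shannon_mean_control <-
      mean(shannon[groupLabels(species) == "control"])
    report$headline$anosim_R <- an$R
    report$headline$anosim_p <- an$p
    mark("diversity")
  }

  diff_species <- NULL
  if (stages["diffabund"] && !is.null(species)) {
    diff_species <- differentialFeatures(species,
                                         alpha_q = config$diffabund$alpha_q)
    f <- file.path(config$outdir, "differential_species.tsv")
    utils::write.table(diff_species, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    report$headline$n_differential_species <- nrow(diff_species)
    truth <- attr(species, "truth")
    if (!is.null(truth)) {
      report$headline$differential_recovery_sensitivity <-
        mean(truth %in% diff_species$feature_id)
    }
    mark("diffabund", config$diffabund)
  }

  if (stages["mlg"] && !is.null(catalog)) {
    markers <- differentialFeatures(geneDepth(catalog), groups =
                                      .group_labels(design),
                                    alpha_q = config$diffabund$alpha_q)
    mlgs <- clusterMarkerGenes(catalog, markers$feature_id)
    mlgs <- assignTaxonomySet(mlgs, geneAnnotation(catalog))
    f <- file.path(config$outdir, "mlg_taxonomy.tsv")
    utils::write.table(mlgTaxonomy(mlgs), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    if (nrow(mlgAbundances(mlgs))) {
      f <- file.path(config$outdir, "mlg_abundance.tsv")
      writeMatrixTSV(mlgAbundances(mlgs), f, "mlg_id"); add_file(f)
    }
    report$headline$n_mlgs <- length(mlgMembers(mlgs))
    mark("mlg")
  }

  if (stages["network"] && !is.null(diff_species) &&
      nrow(diff_species) >= 4) {
    cfg <- sparccConfig(
      n_permutations = config$network$n_permutations,
      n_dirichlet_draws = config$network$n_dirichlet_draws,
      seed = config$seed)
    sub <- abundances(species)[diff_species$feature_id, , drop = FALSE]
    rho <- sparccCorrelation(sub, cfg)
    pv <- sparccPseudoP(sub, rho, cfg)
    edges <- buildNetwork(rho, pv)
    f <- file.path(config$outdir, "network_edges.tsv")
    utils::write.table(edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    report$headline$n_edges_positive <- sum(edges$sign == "positive")
    report$headline$n_edges_negative <- sum(edges$sign == "negative")
    mark("network", config$network)
  }

  if (stages["select"] && !is.null(mlgs) && length(mlgMembers(mlgs)) >= 2) {
    X <- t(mlgAbundances(mlgs))
    y <- .group_labels(design)
    cfg <- mcConfig(nrow(X), cap = config$select$N,
                    cutoff_grid = config$select$cutoff_grid,
                    seed = config$seed)
    stab <- mcStability(X, y, cfg)
    stab <- cutoffScan(stab, X, y, cfg)
    f <- file.path(config$outdir, "stability_c.tsv")
    utils::write.table(
      data.frame(variable = colnames(X), c = stabilityC(stab)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(f)
    report$headline$n_selected_mlgs <- length(selectedVariables(stab))
    mark("select", config$select)
  }

  if (stages["classify"] && !is.null(species)) {
    cv <- crossValidatedScores(species,
                               n_folds = config$classify$n_folds,
                               n_trials = config$classify$n_trials,
                               seed = config$seed)
    roc <- rocAuc(cv$scores, cv$labels)
    ci <- aucBootstrapCI(cv$scores, cv$labels, seed = config$seed)
    f <- file.path(config$outdir, "roc_points.tsv")
    utils::write.table(roc$roc_points, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    report$headline$auc <- roc$auc
    report$headline$auc_ci_low <- ci[["low"]]
    report$headline$auc_ci_high <- ci[["high"]]
    report$headline$cv_accuracy <- cv$mean_accuracy
    mark("classify", config$classify)
  }

  if (stages["correlate"] && !is.null(species) && !is.null(met)) {
    hm <- correlationHeatmap(species, met$concentrations)
    f <- file.path(config$outdir, "species_metabolite_rho.tsv")
    writeMatrixTSV(hm@rho, f, "species_id"); add_file(f)
    report$headline$n_shown_pairs <- sum(hm@mask)
    mark("correlate")
  }

  if (stages["preclinical"]) {
    arms <- config$preclinical$arms
    mo <- simulateMouseExperiment(arms, seed = config$seed)
    f <- file.path(config$outdir, "mouse_outcomes.tsv")
    utils::write.table(mo, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(f)
    inc <- table(mo$arm, mo$aneurysm)
    ft <- fisherExact2x2(inc[, c("TRUE", "FALSE")])
    report$headline$mouse_incidence_fisher_p <- ft$p.value
    lr <- tryCatch(logrankTest(mo), warning = function(w) NULL,
                   error = function(e) NULL)
    if (!is.null(lr)) report$headline$mouse_logrank_p <- lr$p.value
    mark("preclinical")
  }

  report_path <- file.path(config$outdir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$manifest <- c(report$manifest, report_path)
  invisible(report)
}
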