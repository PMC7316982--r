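test_that("identical design and seed reproduce every output bit-identically", {
  d <- cohortDesign(n_per_group = 10, n_genes = 80, n_clusters = 1,
                    cluster_size_range = c(55, 60), n_species = 15,
                    n_metabolites = 6, seed = 5)
  a <- simulateGeneCatalog(d)
  b <- simulateGeneCatalog(d)
  expect_identical(geneDepth(a$catalog), geneDepth(b$catalog))
  expect_identical(geneAnnotation(a$catalog), geneAnnotation(b$catalog))
  sp1 <- simulateTaxonTable(d, "species")
  sp2 <- simulateTaxonTable(d, "species")
  expect_identical(abundances(sp1), abundances(sp2))
  m1 <- simulateMetabolites(d, sp1)
  m2 <- simulateMetabolites(d, sp2)
  expect_identical(m1$concentrations, m2$concentrations)
  arms <- data.frame(label = "a", n = 5, p_aneurysm = 0.5, p_rupture = 0.5)
  expect_identical(simulateMouseExperiment(arms, seed = 2),
                   simulateMouseExperiment(arms, seed = 2))
})

test_that("taxon tables are compositional and carry truth separately", {
  d <- cohortDesign(n_per_group = 15, n_species = 25, seed = 3)
  for (level in c("species", "genus")) {
    tab <- simulateTaxonTable(d, level)
    expect_true(all(abs(colSums(abundances(tab)) - 1) < 1e-9))
    expect_true(all(abundances(tab) >= 0))
    truth <- attr(tab, "truth")
    expect_true(all(truth %in% rownames(abundances(tab))))
    # planted truth must not be recoverable from the table itself
    expect_false(any(grepl("diff|truth", rownames(abundances(tab)))))
  }
})

test_that("zero-effect gene catalog shows nominal per-gene rejection rates", {
  d <- cohortDesign(n_per_group = 30, n_genes = 300, n_clusters = 1,
                    cluster_size_range = c(51, 51), effect_log2fc = 0,
                    noise_sd = 0.3, seed = 11)
  gc <- simulateGeneCatalog(d)
  grp <- rep(c("case", "control"), each = 30)
  res <- differentialFeatures(geneDepth(gc$catalog), groups = grp, all = TRUE)
  # background genes are independent: raw rejection near 5%
  bg <- is.na(trueClusters(gc$catalog))
  rate <- mean(res$p[res$feature_id %in% names(which(bg))] < 0.05)
  se <- sqrt(0.05 * 0.95 / sum(bg))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("planted clusters are internally correlated, background is not", {
  d <- cohortDesign(n_per_group = 50, n_genes = 700, n_clusters = 10,
                    cluster_size_range = c(60, 60), noise_sd = 0.3, seed = 7)
  gc <- simulateGeneCatalog(d)
  L <- log(geneDepth(gc$catalog))
  truth <- trueClusters(gc$catalog)
  in1 <- names(truth)[!is.na(truth) & truth == "cluster_01"][1:15]
  in2 <- names(truth)[!is.na(truth) & truth == "cluster_02"][1:15]
  within <- cor(t(L[in1, ]))
  between <- cor(t(L[in1, ]), t(L[in2, ]))
  expect_gt(mean(within[upper.tri(within)]), mean(between))
  expect_gt(mean(within[upper.tri(within)]), 0.8)
})

test_that("cluster sizing beyond the catalog errors", {
  d <- cohortDesign(n_per_group = 5, n_genes = 100, n_clusters = 2,
                    cluster_size_range = c(60, 60), seed = 1)
  expect_error(simulateGeneCatalog(d), "exceed")
})

test_that("metabolite links hit the target correlation; no-link null holds", {
  d <- cohortDesign(n_per_group = 50, n_species = 20, n_metabolites = 10,
                    target_rho = 0.99, seed = 13)
  sp <- simulateTaxonTable(d, "species")
  met <- simulateMetabolites(d, sp)
  linked <- which(!is.na(met$linked_species))
  expect_gt(length(linked), 0)
  for (j in linked) {
    rho <- spearmanCor(abundances(sp)[met$linked_species[j], ],
                       met$concentrations[j, ])$rho
    expect_gte(rho, 0.9)
  }
  d0 <- cohortDesign(n_per_group = 50, n_species = 20, n_metabolites = 10,
                     target_rho = 0, seed = 13)
  met0 <- simulateMetabolites(d0, sp)
  expect_true(all(is.na(met0$linked_species)))
  # unlinked metabolites stay uncorrelated with every species
  rhos <- apply(abundances(sp), 1, function(s)
    spearmanCor(s, met0$concentrations[1, ])$rho)
  expect_true(mean(abs(rhos) < 0.4) >= 0.95)
})

test_that("mouse generator respects degenerate and large-sample behaviour", {
  arms1 <- data.frame(label = "all", n = 30, p_aneurysm = 1, p_rupture = 1)
  mo <- simulateMouseExperiment(arms1, seed = 5)
  expect_true(all(mo$aneurysm) && all(mo$rupture))
  expect_true(all(mo$onset_day >= 1 & mo$onset_day <= 21))
  expect_true(all(mo$rupture <= mo$aneurysm))  # rupture implies aneurysm

  arms2 <- data.frame(label = "half", n = 10000, p_aneurysm = 0.5,
                      p_rupture = 0.5)
  mo2 <- simulateMouseExperiment(arms2, seed = 6)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_true(sum(mo2$aneurysm) >= ci[1] && sum(mo2$aneurysm) <= ci[2])
  expect_true(all(mo2$onset_day[!mo2$rupture] == 21))
})

test_that("invalid designs are rejected", {
  expect_error(cohortDesign(n_per_group = 0), "positive")
  expect_error(cohortDesign(frac_differential_clusters = 1.2), "fractions")
  expect_error(cohortDesign(target_rho = 1), "target_rho")
})
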