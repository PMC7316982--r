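make_catalog <- function(depth, lengths = rep(1000, nrow(depth))) {
  GeneCatalog(depth, lengths)
}

test_that("two planted clusters are recovered exactly", {
  d <- cohortDesign(n_per_group = 30, n_genes = 120, n_clusters = 2,
                    cluster_size_range = c(60, 60), noise_sd = 0.2,
                    frac_differential_clusters = 0, seed = 23)
  gc <- simulateGeneCatalog(d)
  mlgs <- clusterMarkerGenes(gc$catalog, rownames(geneDepth(gc$catalog)))
  expect_length(mlgMembers(mlgs), 2)
  truth <- trueClusters(gc$catalog)
  assign <- rep(NA_character_, length(truth))
  names(assign) <- names(truth)
  for (m in names(mlgMembers(mlgs))) assign[mlgMembers(mlgs)[[m]]] <- m
  expect_gte(ari(truth, assign), 0.95)
})

test_that("uncorrelated genes form no MLG; >50 threshold is strict", {
  set.seed(51)
  depth <- matrix(rlnorm(60 * 40), 60, 40,
                  dimnames = list(sprintf("g%02d", 1:60),
                                  sprintf("s%02d", 1:40)))
  cat60 <- make_catalog(depth)
  expect_length(mlgMembers(clusterMarkerGenes(cat60, rownames(depth))), 0)

  # a perfect 50-gene cluster is below the ">50 genes" bar
  base <- rlnorm(40)
  d50 <- t(sapply(1:50, function(i) base * exp(rnorm(40, 0, 0.05))))
  rownames(d50) <- sprintf("c%02d", 1:50)
  colnames(d50) <- sprintf("s%02d", 1:40)
  cat50 <- make_catalog(d50)
  expect_length(mlgMembers(clusterMarkerGenes(cat50, rownames(d50))), 0)
  # one more gene and it qualifies
  d51 <- rbind(d50, c51 = base * exp(rnorm(40, 0, 0.05)))
  expect_length(
    mlgMembers(clusterMarkerGenes(make_catalog(d51), rownames(d51))), 1)
})

test_that("clustering is deterministic and partitions the markers", {
  d <- cohortDesign(n_per_group = 20, n_genes = 200, n_clusters = 3,
                    cluster_size_range = c(55, 60), noise_sd = 0.3, seed = 29)
  gc <- simulateGeneCatalog(d)
  ids <- rownames(geneDepth(gc$catalog))
  m1 <- clusterMarkerGenes(gc$catalog, ids)
  m2 <- clusterMarkerGenes(gc$catalog, ids)
  expect_identical(mlgMembers(m1), mlgMembers(m2))
  all_members <- unlist(mlgMembers(m1), use.names = FALSE)
  expect_false(any(duplicated(all_members)))
  expect_true(all(lengths(mlgMembers(m1)) > 50))
})

test_that("MLG abundance is the length-weighted mean and is linear", {
  depth <- rbind(g1 = c(2, 4), g2 = c(4, 0))
  colnames(depth) <- c("s1", "s2")
  cat_eq <- make_catalog(depth, c(500, 500))
  expect_equal(unname(mlgAbundance(c("g1", "g2"), cat_eq)["s1"]), 3)
  cat_w <- make_catalog(depth, c(100, 300))
  # lengths (100, 300), abundances (4, 0) -> 100*4/400 = 1
  expect_equal(unname(mlgAbundance(c("g1", "g2"), cat_w)["s2"]), 1)
  expect_equal(mlgAbundance("g1", cat_eq), depth["g1", ])
  # linearity in member abundances
  cat_scaled <- make_catalog(depth * 7, c(100, 300))
  expect_equal(mlgAbundance(c("g1", "g2"), cat_scaled),
               7 * mlgAbundance(c("g1", "g2"), cat_w))
  expect_error(mlgAbundance(character(), cat_eq), "empty")
})

test_that("taxonomy voting applies the species/genus cascade", {
  genes <- sprintf("g%03d", 1:100)
  # 90/100 at 96% identity, 0.8 overlap -> species (boundary inclusive)
  ann <- make_annotation(genes, 90, species = "S1", dna = 96, overlap = 0.8)
  res <- assignTaxonomy(genes, ann)
  expect_equal(res$level, "species")
  expect_equal(res$name, "S1")
  expect_equal(res$fraction, 0.90)

  # 89 qualify for species but 85 qualify for genus -> genus
  ann2 <- make_annotation(genes, 89, species = "S1", genus = "G1",
                          dna = 96, protein = 80, overlap = 0.8)
  # make 85 of the 89 also genus-qualified (protein >= 85)
  ann2$protein_identity[1:85] <- 90
  res2 <- assignTaxonomy(genes, ann2)
  expect_equal(res2$level, "genus")
  expect_equal(res2$name, "G1")

  # no annotations -> unclassified
  res3 <- assignTaxonomy(genes, ann[0, ])
  expect_equal(res3$level, "unclassified")
  expect_true(is.na(res3$name))
})

test_that("taxonomy thresholds are inclusive at every boundary", {
  genes <- sprintf("g%03d", 1:100)
  # exactly 90% of genes, exactly 95% identity, exactly 70% overlap
  ann <- make_annotation(genes, 90, species = "S", dna = 95, overlap = 0.70)
  expect_equal(assignTaxonomy(genes, ann)$level, "species")
  # one vote short of 90% -> cascade fails species
  ann89 <- make_annotation(genes, 89, species = "S", dna = 95, overlap = 0.70)
  expect_false(assignTaxonomy(genes, ann89)$level == "species")
  # genus boundary: exactly 80% at 85/85
  annG <- make_annotation(genes, 80, genus = "G", dna = 85, protein = 85,
                          overlap = 0.1)
  annG$species_hit <- NA
  expect_equal(assignTaxonomy(genes, annG)$level, "genus")
  # identity just below threshold disqualifies
  annB <- make_annotation(genes, 95, species = "S", dna = 94.9, overlap = 0.9)
  expect_false(assignTaxonomy(genes, annB)$level == "species")
})
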