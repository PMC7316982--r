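# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately brute-force: enumeration and closed forms
# that stay separate from the package's own computational paths.

# Adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  N <- choose(sum(tab), 2)
  (sij - si * sj / N) / ((si + sj) / 2 - si * sj / N)
}

# Exact two-sided Wilcoxon p by complete enumeration of all C(n1+n2, n1)
# group assignments of the pooled values (no ties assumed).
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher p by enumeration of all tables with the observed margins
# under the point-probability rule.
enumerate_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  prob <- vapply(a_range, function(a) {
    choose(cs[1], a) * choose(cs[2], rs[1] - a) / choose(n, rs[1])
  }, numeric(1))
  stopifnot(abs(sum(prob) - 1) < 1e-12)
  p_obs <- prob[a_range == a_obs]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric enrichment p by enumeration of all possible
# differential sets of the same size within the universe.
enumerate_enrichment_p <- function(universe, term, de_size, k_obs) {
  combos <- utils::combn(length(universe), de_size)
  hits <- apply(combos, 2, function(idx) {
    length(intersect(universe[idx], term))
  })
  mean(hits >= k_obs)
}

# ANOSIM permutation p over ALL distinct relabelings (small n only)
enumerate_anosim_p <- function(d, groups) {
  n <- length(groups)
  idx_a <- which(groups == unique(groups)[1])
  pair <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  M <- length(r)
  stat <- function(g) {
    between <- g[pair[, 1]] != g[pair[, 2]]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R_obs <- stat(groups)
  combos <- utils::combn(n, length(idx_a))
  R_all <- apply(combos, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    stat(g)
  })
  mean(R_all >= R_obs - 1e-12)
}

# Expected rarefaction richness: sum_i (1 - C(N - N_i, m) / C(N, m))
rarefaction_expected <- function(counts, m) {
  N <- sum(counts)
  sum(1 - choose(N - counts, m) / choose(N, m))
}

# Compositional fractions from a log-normal basis with one planted
# correlated pair (features 1 and 2) at latent Pearson correlation r.
sparcc_basis_fixture <- function(D, n, r, seed) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(D * n), D, n)
    L[2, ] <- r * L[1, ] + sqrt(1 - r^2) * L[2, ]
    basis <- exp(L + rnorm(D, 0, 1))
    sweep(basis, 2, colSums(basis), "/")
  })
}

# Tiny annotation fixture: n_hit of n genes hit `species` at the given
# identities/overlap, the rest hit nothing.
make_annotation <- function(gene_ids, n_hit, species = "SpX", genus = "GnX",
                            dna = 96, protein = 90, overlap = 0.8) {
  data.frame(
    gene_id = gene_ids[seq_len(n_hit)],
    species_hit = species, genus_hit = genus,
    dna_identity = dna, protein_identity = protein,
    query_overlap = overlap
  )
}
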