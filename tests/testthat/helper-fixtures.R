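# shared builders for small deterministic fixtures

two_hap_panel <- function(p1 = 0.6, haps = c("A", "a")) {
  hap_panel(haps, c(p1, 1 - p1))
}

# independent loci, every combination of alleles 1/2 over n_loci loci,
# equal frequencies -> MAF 0.5 per locus, no LD
independent_panel <- function(n_loci = 4) {
  haps <- do.call(paste0, expand.grid(rep(list(c("1", "2")), n_loci)))
  hap_panel(haps, rep(1 / length(haps), length(haps)))
}

toy_dataset <- function(G, y) genotype_dataset(as.matrix(G), y)

# small random dataset with both classes guaranteed nonempty
random_dataset <- function(n = 60, q = 4, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * q, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
              n, q)
  y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
  genotype_dataset(G, y)
}

# control-only genotypes straight from the pair law (no disease weighting)
sim_controls <- function(panel, f_st, n) {
  pairs <- sample_haplotype_pairs(panel, pairing_model(f_st), n)
  panel$hap_minor[pairs[, 1], , drop = FALSE] +
    panel$hap_minor[pairs[, 2], , drop = FALSE]
}

# random symmetric positive definite score_stat for algebraic tests
random_score <- function(d = 4, seed = 1, coding = "additive-prospective") {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  v <- crossprod(A) + diag(d) * 0.1
  u <- rnorm(d, sd = 2)
  min2assoc:::new_score_stat(u, v, coding)
}
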