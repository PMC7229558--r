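test_that("codominant coding expands counts into the (het, hom) indicator pairs", {
  d <- toy_dataset(cbind(c(0, 1, 2), c(0, 0, 0), c(2, 1, 0)), c(1, 0, 1))
  X <- codominant_code(d)
  expect_identical(dim(X), c(3L, 6L))
  expect_identical(unname(X[, 1:2]), cbind(c(0L, 1L, 0L), c(0L, 0L, 1L)))
  expect_true(all(X[, 3:4] == 0L))            # monomorphic zero column
  expect_true(all(rowSums(X[, 1:2]) <= 1L))   # at most one indicator per SNP
})

test_that("per-SNP HWE summary matches hand arithmetic", {
  d <- toy_dataset(cbind(c(0, 1, 2, 1)), c(1, 0, 1, 0))
  s <- snp_hwe_summary(d, 1)
  expect_equal(s$maf, 0.5)
  expect_equal(s$hwe_probs, c(0.25, 0.5, 0.25))
  expect_equal(s$pooled_mean, c(0.5, 0.25))
  expect_equal(s$tau, c(0, 0))
  expect_equal(s$weights, c(1, 1))
})

test_that("degenerate indicator variances resolve weights by the tau limit", {
  # all minor homozygotes: s^2 = 0, tau = 0 -> weight 1
  d <- toy_dataset(cbind(c(2, 2, 2, 2), c(0, 1, 2, 1)), c(1, 0, 1, 0))
  s <- snp_hwe_summary(d, 1)
  expect_equal(s$maf, 1)
  expect_equal(s$sample_var, c(0, 0))
  expect_equal(s$weights, c(1, 1))
  # all heterozygotes: s^2 = 0 but tau != 0 -> weight 0
  d <- toy_dataset(cbind(c(1, 1, 1, 1), c(0, 1, 2, 1)), c(1, 0, 1, 0))
  s <- snp_hwe_summary(d, 1)
  expect_equal(s$tau, c(-0.5, 0.25))
  expect_equal(s$weights, c(0, 0))
})

test_that("prospective score matches the two-sample hand computation", {
  d <- toy_dataset(cbind(c(0, 2)), c(1, 0))
  sc <- prospective_score(d)
  expect_equal(sc$u, -1)
  expect_equal(drop(sc$v), 0.5)
  expect_equal(sc$coding, "additive-prospective")
})

test_that("scores are invariant to sample reordering", {
  d <- random_dataset(40, 3, seed = 2)
  set.seed(9)
  perm <- sample(40)
  dp <- genotype_dataset(d$genotypes[perm, ], d$phenotype[perm])
  expect_equal(prospective_score(dp)$u, prospective_score(d)$u)
  expect_equal(prospective_score(dp)$v, prospective_score(d)$v,
               ignore_attr = TRUE)
  expect_equal(eb_score(dp)$u, eb_score(d)$u, ignore_attr = TRUE)
})

test_that("EB score hits the retrospective sum when the pooled sample is HWE-exact", {
  # counts (1, 2, 1) at f = 0.5 are exactly HWE -> tau = 0, W = I
  d <- toy_dataset(cbind(c(0, 1, 1, 2)), c(1, 1, 0, 0))
  s <- snp_hwe_summary(d, 1)
  expect_equal(s$weights, c(1, 1))
  sc <- eb_score(d)
  X <- codominant_code(d)
  retro <- colSums(X[d$phenotype == 1, , drop = FALSE]) - 2 * s$hwe_probs[2:3]
  expect_equal(unname(sc$u), unname(retro))
})

test_that("EB machinery with zero weights reduces to the prospective case sum", {
  for (seed in 1:5) {
    d <- random_dataset(50, 4, seed = seed)
    X <- codominant_code(d)
    u0 <- min2assoc:::eb_case_sum(X, d$phenotype, rep(0, 8), rep(0, 8))
    prosp <- colSums(X[d$phenotype == 1, , drop = FALSE]) -
      sum(d$phenotype) * colMeans(X)
    expect_equal(unname(u0), unname(prosp))
    # and with additive codes it reproduces the prospective score exactly
    ua <- min2assoc:::eb_case_sum(d$genotypes, d$phenotype,
                                  rep(0, 4), rep(0, 4))
    expect_equal(unname(ua), unname(prospective_score(d)$u))
  }
})

test_that("the prospective component has exact zero mean over label permutations", {
  G <- cbind(c(0, 1, 2, 1, 0, 2))
  X <- codominant_code(toy_dataset(G, c(1, 1, 1, 0, 0, 0)))
  idx <- utils::combn(6, 3)
  sums <- apply(idx, 2, function(cs)
    colSums(X[cs, , drop = FALSE]) - 3 * colMeans(X))
  expect_equal(unname(rowMeans(sums)), c(0, 0))
})

test_that("EB covariance limits and shape contracts hold", {
  d <- random_dataset(80, 3, seed = 7)
  # fixed zero weights: exactly the prospective covariance of the codes
  Xc <- scale(codominant_code(d), center = TRUE, scale = FALSE)
  ybar <- mean(d$phenotype)
  vp <- ybar * (1 - ybar) * crossprod(Xc)
  expect_equal(eb_covariance(d, weights = rep(0, 6)), vp,
               ignore_attr = TRUE, tolerance = 1e-12)
  # adaptive estimator: symmetric PSD, at least as large on the diagonal
  vb <- eb_covariance(d)
  expect_equal(vb, t(vb))
  ev <- eigen(vb, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_true(all(diag(vb) >= diag(vp) - 1e-10))
})

test_that("the oracle score supports the three genetic codings", {
  d <- toy_dataset(cbind(c(0, 2)), c(1, 0))
  sc <- gold_score(d, 1)
  expect_equal(c(sc$u, drop(sc$v)), c(-1, 0.5))
  d2 <- toy_dataset(cbind(c(0, 1, 2, 2), c(0, 1, 0, 1)), c(1, 0, 1, 0))
  g_rec <- as.integer(d2$genotypes[, 1] == 2)
  sc_rec <- gold_score(d2, 1, "recessive")
  expect_equal(sc_rec$u, sum((d2$phenotype - 0.5) * g_rec))
  expect_error(gold_score(toy_dataset(cbind(c(1, 1), c(0, 1)), c(1, 0)), 1,
                          "recessive"), "monomorphic")
})
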