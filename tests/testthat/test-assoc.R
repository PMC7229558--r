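test_that("component selection follows the explained-variability rule", {
  expect_equal(select_components(c(1, 0, 0)), 1L)
  expect_equal(select_components(c(3, 1, 1), 0.85), 3L)
  expect_equal(select_components(c(9, 1), 0.85), 1L)
  # floored tail eigenvalues do not enter the denominator
  expect_equal(select_components(c(1, 1e-12), 0.85), 1L)
  expect_equal(select_components(c(2, 2), 1), 2L)
  expect_error(select_components(c(0, 0)), "degenerate")
  expect_error(select_components(c(1, 1), 1.2), "threshold")
})

test_that("scalar principal chi-squared equals the 1-df trend-type score test", {
  d <- toy_dataset(cbind(c(0, 2)), c(1, 0))
  tt <- principal_chisq(prospective_score(d))
  expect_equal(tt$statistic, 2)          # U^2/V = 1/0.5
  expect_equal(tt$df, 1L)
  expect_equal(tt$p_value, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(tt$method, "PChiP")
})

test_that("full-rank principal chi-squared equals Hotelling T2 = U V^-1 U^T", {
  for (seed in 1:6) {
    sc <- random_score(d = 4, seed = seed)
    t2 <- hotelling_t2(sc)
    expect_equal(t2$statistic,
                 drop(sc$u %*% solve(sc$v, sc$u)), tolerance = 1e-10)
    expect_equal(t2$df, 4L)
    expect_equal(t2$statistic, principal_chisq(sc, threshold = 1)$statistic)
  }
  # hand case: V = diag(2, 2), U = (2, 2) -> T2 = 4
  sc <- min2assoc:::new_score_stat(c(2, 2), diag(2, 2), "additive-prospective")
  expect_equal(hotelling_t2(sc)$statistic, 4)
})

test_that("the statistic is invariant under joint orthogonal rotation of U and V", {
  for (seed in 1:5) {
    sc <- random_score(d = 4, seed = seed)
    set.seed(seed + 100)
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
    scr <- min2assoc:::new_score_stat(drop(crossprod(Q, sc$u)),
                                      crossprod(Q, sc$v %*% Q),
                                      sc$coding)
    expect_equal(principal_chisq(scr, 0.85)$statistic,
                 principal_chisq(sc, 0.85)$statistic, tolerance = 1e-8)
    expect_equal(hotelling_t2(scr)$statistic, hotelling_t2(sc)$statistic,
                 tolerance = 1e-8)
  }
})

test_that("duplicated SNP columns leave the retained-rank T2 unchanged", {
  d <- random_dataset(100, 3, seed = 3)
  ddup <- genotype_dataset(cbind(d$genotypes, d$genotypes[, 3]), d$phenotype)
  t_base <- hotelling_t2(prospective_score(d))
  t_dup <- hotelling_t2(prospective_score(ddup))
  expect_equal(t_dup$diagnostics$rank, t_base$diagnostics$rank)
  expect_equal(t_dup$statistic, t_base$statistic, tolerance = 1e-6)
})

test_that("SSUP is the sum of squared scores with the eigen-decomposition identity", {
  sc <- min2assoc:::new_score_stat(c(3, 4), diag(2), "additive-prospective")
  expect_equal(ssup_test(sc)$statistic, 25)
  for (seed in 1:5) {
    sc <- random_score(d = 5, seed = seed)
    eg <- eigen(sc$v, symmetric = TRUE)
    za <- drop(sc$u %*% eg$vectors)
    expect_equal(sum(eg$values * za^2 / eg$values), sum(sc$u^2),
                 tolerance = 1e-10)
    expect_equal(ssup_test(sc)$statistic, sum(sc$u^2))
  }
})

test_that("single-eigenvalue SSUP p-value collapses to the chi-squared p-value", {
  d <- toy_dataset(cbind(c(0, 1, 2, 1, 0, 2)), c(1, 0, 1, 0, 0, 1))
  sc <- prospective_score(d)
  expect_equal(ssup_test(sc)$p_value,
               pchisq(sc$u^2 / drop(sc$v), 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("weighted chi-squared mixture tail is exact for one component and sane for several", {
  expect_equal(pchisq_mixture(3.2, 2), pchisq(1.6, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # two equal weights: 2 * chi2_2
  expect_equal(pchisq_mixture(7, c(1, 1)), pchisq(7, 2, lower.tail = FALSE),
               tolerance = 1e-6)
  # exact reference for unequal weights: Imhof characteristic-function
  # inversion, computed here as the oracle
  lam <- c(3, 1, 0.5)
  imhof <- function(q) {
    f <- function(u) {
      th <- 0.5 * rowSums(outer(u, lam, function(uu, l) atan(l * uu))) -
        q * u / 2
      rho <- exp(0.25 * rowSums(outer(u, lam,
                                      function(uu, l) log1p(l^2 * uu^2))))
      ifelse(u == 0, 0.5 * (sum(lam) - q), sin(th) / (u * rho))
    }
    0.5 + integrate(f, 0, 200, rel.tol = 1e-9,
                    subdivisions = 5000L)$value / pi
  }
  # the moment-matching approximation targets the tail: relative accuracy
  # tightens as the tail probability shrinks
  for (qv in c(5, 10, 15, 20)) {
    ref <- imhof(qv)
    err <- abs(pchisq_mixture(qv, lam) - ref)
    expect_lt(err, 0.01)
    if (ref < 0.15) expect_lt(err / ref, 0.05)
  }
  expect_error(pchisq_mixture(1, c(0, 0)), "zero")
})

test_that("GOLD test matches its hand-computed example and label symmetry", {
  d <- toy_dataset(cbind(c(0, 2)), c(1, 0))
  g <- gold_test(d, 1)
  expect_equal(g$statistic, 2)
  expect_equal(g$p_value, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  d2 <- random_dataset(60, 2, seed = 8)
  flip <- genotype_dataset(d2$genotypes, 1L - d2$phenotype)
  expect_equal(gold_test(flip, 1)$statistic, gold_test(d2, 1)$statistic,
               tolerance = 1e-10)
})

test_that("GOLD null permutation distribution matches chi-squared with 1 df", {
  set.seed(14)
  d <- random_dataset(400, 2, seed = 14)
  n1 <- sum(d$phenotype)
  stats <- replicate(1500, {
    yp <- integer(400)
    yp[sample.int(400, n1)] <- 1L
    gold_test(genotype_dataset(d$genotypes, yp), 1)$statistic
  })
  expect_gt(suppressWarnings(ks.test(stats, pchisq, df = 1))$p.value, 0.01)
})

test_that("Min2 takes the minimum p-value and obeys the add-one floor", {
  set.seed(15)
  p <- nat2_panel()
  d <- simulate_dataset(p, pairing_model(0), disease_model(2, "recessive", 3),
                        300, 300)
  m2 <- min2_test(d, n_perm = 60)
  expect_equal(m2$statistic,
               min(principal_chisq(prospective_score(d))$p_value,
                   principal_chisq(eb_score(d))$p_value),
               tolerance = 1e-10)
  expect_gte(m2$p_value, 1 / 61)
  expect_lte(m2$p_value, 1)
  expect_error(min2_test(d, n_perm = 0), "n_perm")
})
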