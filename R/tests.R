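#' Select the number of principal components by explained variability
#'
#' Given eigenvalues sorted in descending order, returns the smallest `s`
#' whose leading eigenvalues account for at least `threshold` of the total,
#' computed over the retained eigenvalues only: eigenvalues below
#' `1e-8 * max(eigenvalues)` (numerical rank floor) are dropped before the
#' cumulative fractions are formed, so duplicated or monomorphic columns do
#' not inflate the apparent variability.
#'
#' @param eigenvalues nonnegative values in descending order.
#' @param threshold fraction of variability to capture, in (0, 1\];
#'   default 0.85.
#' @return Integer `s >= 1`.
#' @export
select_components <- function(eigenvalues, threshold = 0.85) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ev <- eigenvalues[eigenvalues >= 1e-8 * max(eigenvalues, 0)]
  if (length(ev) == 0L || max(ev) <= 0)
    stop("degenerate input: all eigenvalues are zero")
  frac <- cumsum(ev) / sum(ev)
  # guard against cumulative rounding leaving frac[last] slightly below 1
  frac[length(frac)] <- 1
  as.integer(which(frac >= threshold - 1e-12)[1L])
}

new_test_result <- function(method, statistic, df, p_value, diagnostics = list()) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, diagnostics = diagnostics),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f%s, p = %.4g\n", x$method,
              x$statistic,
              if (is.null(x$df) || is.na(x$df)) "" else sprintf(" (df = %d)", x$df),
              x$p_value))
  invisible(x)
}

#' Principal chi-squared test
#'
#' Eigendecomposes the estimated score covariance `V`, keeps the top `s`
#' components explaining `threshold` of the retained variability
#' ([select_components()]), and forms
#' \deqn{\sum_{k \le s} (U \xi_k)^2 / \lambda_k \sim \chi^2_s} under the
#' null. Applied to the additive prospective score this is the principal
#' components regression score test (PChiP); applied to the codominant
#' empirical-Bayes score it is PChiB.
#'
#' @param score a `score_stat` (see [prospective_score()], [eb_score()]).
#' @param threshold explained-variability fraction; `1` keeps the full
#'   retained rank (Hotelling T2).
#' @param method label recorded on the result; defaults to a tag derived
#'   from the score's coding.
#' @return An `assoc_test` with diagnostics `s`, `rank` (retained rank),
#'   `eigenvalues` and `eigenvectors`.
#' @export
principal_chisq <- function(score, threshold = 0.85, method = NULL) {
  stopifnot(inherits(score, "score_stat"))
  eg <- eigen(score$v, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- lam >= 1e-8 * max(lam, 0)
  if (!any(keep)) stop("degenerate input: all eigenvalues are zero")
  lam <- lam[keep]
  xi <- eg$vectors[, keep, drop = FALSE]
  s <- select_components(lam, threshold)
  z2 <- drop(crossprod(xi, score$u))^2 / lam
  stat <- sum(z2[seq_len(s)])
  if (is.null(method))
    method <- switch(score$coding,
                     "additive-prospective" = "PChiP",
                     "codominant-empirical-bayes" = "PChiB",
                     "PChi")
  new_test_result(method, stat, df = s,
                  p_value = stats::pchisq(stat, df = s, lower.tail = FALSE),
                  diagnostics = list(s = s, rank = length(lam),
                                     eigenvalues = lam, eigenvectors = xi))
}

#' Hotelling T2 test on the retained rank
#'
#' The full-rank version of [principal_chisq()]: all retained eigencomponents
#' contribute, so the statistic equals \eqn{U V^- U^T} (pseudo-inverse on
#' the retained subspace) with degrees of freedom equal to the retained rank.
#'
#' @inheritParams principal_chisq
#' @return An `assoc_test` with method tag `"T2"`.
#' @export
hotelling_t2 <- function(score) {
  principal_chisq(score, threshold = 1, method = "T2")
}

#' Sum of squared scores test (SSUP)
#'
#' The statistic \eqn{\sum_k U_k^2} on the additive prospective score. Its
#' null law is the eigenvalue-weighted chi-squared mixture
#' \eqn{\sum_k \tilde\lambda_k \chi^2_1}; the p-value uses
#' [pchisq_mixture()]. Unlike the principal chi-squared test, SSUP weights
#' every component by its eigenvalue rather than truncating, so its power
#' profile depends strongly on the LD structure.
#'
#' @param score a `score_stat` (normally from [prospective_score()]).
#' @param method p-value method passed to [pchisq_mixture()].
#' @return An `assoc_test` with method tag `"SSUP"`.
#' @export
ssup_test <- function(score, method = c("liu", "satterthwaite")) {
  stopifnot(inherits(score, "score_stat"))
  method <- match.arg(method)
  stat <- sum(score$u^2)
  lam <- eigen(score$v, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam[lam >= 1e-8 * max(lam, 0)]
  new_test_result("SSUP", stat, df = NA_integer_,
                  p_value = pchisq_mixture(stat, lam, method = method),
                  diagnostics = list(eigenvalues = lam))
}

#' Oracle single-SNP test (GOLD)
#'
#' The 1-df chi-squared score test `U^2 / V` on the known causal column
#' ([gold_score()]). A simulation-only benchmark: it uses information (the
#' causal SNP identity) unavailable in real analyses.
#'
#' @param data a [genotype_dataset()].
#' @param causal 1-based causal column index.
#' @param coding the causal SNP's true genetic code (see [gold_score()]).
#' @return An `assoc_test` with method tag `"GOLD"`.
#' @export
gold_test <- function(data, causal,
                      coding = c("additive", "dominant", "recessive")) {
  sc <- gold_score(data, causal, coding)
  stat <- sc$u^2 / drop(sc$v)
  new_test_result("GOLD", stat, df = 1L,
                  p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Min2: permutation-calibrated minimum of the PChiP and PChiB p-values
#'
#' The observed statistic is the smaller of the asymptotic p-values of
#' PChiP (additive prospective principal chi-squared) and PChiB (codominant
#' empirical-Bayes principal chi-squared). Because the minimum of two
#' dependent p-values is not itself uniform, the p-value is calibrated by
#' case-control label permutation with the add-one estimator
#' \eqn{(1 + \#\{Min2_{perm} \le Min2_{obs}\}) / (B + 1)}.
#'
#' All pooled-sample quantities entering the two tests — allele
#' frequencies, shrinkage weights, the covariance estimates and hence the
#' eigenvectors, eigenvalues and selected component counts — are invariant
#' under label permutation, so only the case sums are recomputed per
#' permutation (a fast matrix product).
#'
#' @param data a [genotype_dataset()].
#' @param threshold explained-variability fraction for both component
#'   selections.
#' @param n_perm number of label permutations (at least 1); 200 by default.
#' @return An `assoc_test` with method tag `"Min2"`; `statistic` is the
#'   observed minimum p-value, `p_value` the permutation p-value, and
#'   diagnostics carry the two asymptotic p-values and component counts.
#' @export
min2_test <- function(data, threshold = 0.85, n_perm = 200) {
  stopifnot(inherits(data, "genotype_dataset"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  y <- data$phenotype
  n <- length(y)
  n1 <- sum(y == 1L)
  ybar <- n1 / n

  sp <- prospective_score(data)
  sb <- eb_score(data)
  tp <- principal_chisq(sp, threshold)
  tb <- principal_chisq(sb, threshold)
  obs <- min(tp$p_value, tb$p_value)

  # projections whose case-column-sums give the component scores U xi_k
  s1 <- tp$diagnostics$s
  s2 <- tb$diagnostics$s
  A1 <- data$genotypes %*% tp$diagnostics$eigenvectors[, seq_len(s1), drop = FALSE]
  X <- codominant_code(data)
  B2 <- X %*% tb$diagnostics$eigenvectors[, seq_len(s2), drop = FALSE]
  # fixed pooled centers: U_P uses Ybar * colsum, U_B uses the blended center
  off1 <- ybar * colSums(A1)
  q <- ncol(data$genotypes)
  summ <- lapply(seq_len(q), function(k) snp_hwe_summary(data, k))
  w <- unlist(lapply(summ, `[[`, "weights"))
  e_hwe <- unlist(lapply(summ, function(s) s$hwe_probs[2:3]))
  blend <- w * e_hwe + (1 - w) * colMeans(X)
  off2 <- n1 * drop(crossprod(tb$diagnostics$eigenvectors[, seq_len(s2), drop = FALSE], blend))

  lam1 <- tp$diagnostics$eigenvalues[seq_len(s1)]
  lam2 <- tb$diagnostics$eigenvalues[seq_len(s2)]

  Yp <- matrix(0, nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) Yp[sample.int(n, n1), b] <- 1
  U1 <- crossprod(A1, Yp) - off1          # s1 x B
  U2 <- crossprod(B2, Yp) - off2          # s2 x B
  stat1 <- colSums(U1^2 / lam1)
  stat2 <- colSums(U2^2 / lam2)
  pmin2 <- pmin(stats::pchisq(stat1, df = s1, lower.tail = FALSE),
                stats::pchisq(stat2, df = s2, lower.tail = FALSE))
  pval <- (1 + sum(pmin2 <= obs)) / (n_perm + 1)
  new_test_result("Min2", obs, df = NA_integer_, p_value = pval,
                  diagnostics = list(p_pchip = tp$p_value, p_pchib = tb$p_value,
                                     s_pchip = s1, s_pchib = s2,
                                     n_perm = n_perm))
}
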