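#' Haplotype-pair law with inbreeding
#'
#' The ordered-pair law used by the simulator:
#' \deqn{\phi_{HH'} = (1 - F_{st}) f_H f_{H'} + \delta_{HH'} F_{st} f_H,}
#' where \eqn{F_{st}} is the fixation (inbreeding) parameter and
#' \eqn{\delta_{HH'}} indicates \eqn{H = H'}. At \eqn{F_{st} = 0} the two
#' haplotypes of an individual are independent draws (Hardy-Weinberg
#' equilibrium); at \eqn{F_{st} = 1} every individual is fully homozygous.
#'
#' @param f_st fixation parameter in \[0, 1\].
#' @return An object of class `pairing_model`.
#' @export
pairing_model <- function(f_st = 0) {
  f_st <- as.numeric(f_st)
  if (length(f_st) != 1L || !is.finite(f_st) || f_st < 0 || f_st > 1)
    stop("f_st must be a single number in [0, 1]")
  structure(list(f_st = f_st), class = "pairing_model")
}

#' Single-locus disease model for case sampling
#'
#' Cases are over-sampled according to their genotype at one designated
#' causal locus: a haplotype pair that is heterozygous there receives odds
#' ratio `r_Aa`, a minor-allele homozygote receives `r_aa`. The standard
#' genetic modes map a single odds ratio theta to the pair
#' (`r_Aa`, `r_aa`): additive (theta, theta^2) — multiplicative per
#' allele on the odds scale —, dominant (theta, theta), recessive
#' (1, theta). `r_Aa = r_aa = 1` is the null model.
#'
#' @param causal 1-based causal locus index.
#' @param mode one of `"additive"`, `"dominant"`, `"recessive"`, `"null"`,
#'   `"custom"`.
#' @param theta the mode's odds ratio (ignored for `"null"` and `"custom"`).
#' @param r_Aa,r_aa explicit odds ratios, required for `mode = "custom"`.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(causal, mode = c("additive", "dominant", "recessive",
                                           "null", "custom"),
                          theta = 1, r_Aa = NULL, r_aa = NULL) {
  mode <- match.arg(mode)
  causal <- as.integer(causal)
  if (length(causal) != 1L || is.na(causal) || causal < 1L)
    stop("causal must be a positive locus index")
  ors <- switch(mode,
    additive  = c(theta, theta^2),
    dominant  = c(theta, theta),
    recessive = c(1, theta),
    null      = c(1, 1),
    custom    = {
      if (is.null(r_Aa) || is.null(r_aa))
        stop("custom mode requires r_Aa and r_aa")
      c(r_Aa, r_aa)
    })
  if (any(!is.finite(ors)) || any(ors < 0))
    stop("odds ratios must be finite and >= 0")
  structure(list(causal = causal, mode = mode,
                 r_Aa = ors[[1L]], r_aa = ors[[2L]]),
            class = "disease_model")
}

is_null_model <- function(disease) disease$r_Aa == 1 && disease$r_aa == 1

#' Sample ordered haplotype pairs
#'
#' Draws `n` ordered haplotype pairs from the pair law of
#' [pairing_model()]: with probability `f_st` a single haplotype is drawn
#' from the panel frequencies and duplicated, otherwise the two haplotypes
#' are drawn independently. This mixture reproduces the ordered-pair law
#' exactly.
#'
#' @param panel a [hap_panel()].
#' @param pairing a [pairing_model()].
#' @param n number of pairs.
#' @return Integer matrix `n x 2` of haplotype indices into the panel.
#' @export
sample_haplotype_pairs <- function(panel, pairing, n) {
  stopifnot(inherits(panel, "hap_panel"), inherits(pairing, "pairing_model"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  nh <- length(panel$haplotypes)
  h1 <- sample.int(nh, n, replace = TRUE, prob = panel$frequencies)
  h2 <- sample.int(nh, n, replace = TRUE, prob = panel$frequencies)
  if (pairing$f_st > 0) {
    dup <- stats::runif(n) < pairing$f_st
    h2[dup] <- h1[dup]
  }
  cbind(h1, h2, deparse.level = 0)
}

#' Case distribution over ordered haplotype pairs
#'
#' The case pair law: each ordered pair (H, H') is weighted by
#' \deqn{R_{Aa}^{I(Aa)} R_{aa}^{I(aa)} \phi_{HH'}} at the causal locus and
#' the weights are renormalized. With null odds ratios this is exactly the
#' control pair law.
#'
#' @inheritParams sample_haplotype_pairs
#' @param disease a [disease_model()]; its causal locus must be polymorphic
#'   in the panel.
#' @return A list with `prob` (n_hap x n_hap matrix of ordered-pair
#'   probabilities, rows = first haplotype) and `phi` (the control law).
#' @export
case_pair_weights <- function(panel, pairing, disease) {
  stopifnot(inherits(panel, "hap_panel"), inherits(pairing, "pairing_model"),
            inherits(disease, "disease_model"))
  ck <- disease$causal
  if (ck > panel$q) stop("causal locus index exceeds panel locus count")
  if (panel$monomorphic[ck])
    stop("causal locus is monomorphic in the panel")
  f <- panel$frequencies
  fst <- pairing$f_st
  phi <- (1 - fst) * tcrossprod(f) + fst * diag(f)
  a <- panel$hap_minor[, ck]              # minor-allele indicator per haplotype
  g <- outer(a, a, "+")                   # causal genotype of each ordered pair
  w <- disease$r_Aa^(g == 1L) * disease$r_aa^(g == 2L)
  # r = 0 with matching genotype must kill the pair even where phi = 0
  pr <- phi * w
  pr <- pr / sum(pr)
  list(prob = pr, phi = phi)
}

#' Case-control genotype datasets
#'
#' Container for an `n x q` matrix of minor-allele counts (0/1/2) and a
#' binary phenotype. Both phenotype classes must be nonempty and no missing
#' genotypes are allowed (see [read_vcf_genotypes()] for the preprocessing
#' rules applied to real data).
#'
#' @param genotypes integer/numeric matrix with entries in \{0, 1, 2\}.
#' @param phenotype binary (0/1) vector, one entry per row of `genotypes`.
#' @param snp_ids optional SNP labels; defaults to the matrix column names
#'   or `SNP1..SNPq`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (nrow(genotypes) != length(phenotype))
    stop("genotypes and phenotype must have matching length")
  if (anyNA(genotypes) || !all(genotypes %in% 0:2))
    stop("genotype entries must be 0, 1 or 2 with no missing values")
  if (!all(phenotype %in% 0:1))
    stop("phenotype must be binary 0/1")
  if (sum(phenotype) == 0L || sum(phenotype) == length(phenotype))
    stop("both phenotype classes must be nonempty")
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_ids = snp_ids),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("Case-control genotype dataset: %d cases / %d controls x %d SNPs\n",
              sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              ncol(x$genotypes)))
  invisible(x)
}

#' Simulate a case-control genotype dataset from a haplotype panel
#'
#' Controls are drawn from the haplotype-pair law of the pairing model;
#' cases are drawn from the odds-ratio-reweighted case pair law of
#' [case_pair_weights()]. Phase is then discarded and each locus converted
#' to its minor-allele count. Cases occupy the first `n_cases` rows with
#' phenotype 1.
#'
#' @inheritParams case_pair_weights
#' @param n_cases,n_controls sample sizes (each at least 1).
#' @return A [genotype_dataset()].
#' @export
simulate_dataset <- function(panel, pairing, disease, n_cases, n_controls) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases < 1L || n_controls < 1L)
    stop("n_cases and n_controls must both be >= 1")
  nh <- length(panel$haplotypes)

  cw <- case_pair_weights(panel, pairing, disease)
  idx <- sample.int(nh * nh, n_cases, replace = TRUE, prob = as.vector(cw$prob))
  case_pairs <- cbind((idx - 1L) %% nh + 1L, (idx - 1L) %/% nh + 1L)
  ctrl_pairs <- sample_haplotype_pairs(panel, pairing, n_controls)

  pairs <- rbind(case_pairs, ctrl_pairs)
  G <- panel$hap_minor[pairs[, 1L], , drop = FALSE] +
       panel$hap_minor[pairs[, 2L], , drop = FALSE]
  genotype_dataset(G, rep(c(1L, 0L), c(n_cases, n_controls)))
}

# Deterministic per-replicate substream seed from (master, cell, replicate).
# Simple 32-bit-safe multiplicative mixing; collisions across the lattice of
# study cells are what matters and are astronomically unlikely.
derive_seed <- function(master, ...) {
  h <- as.double(master %% 2147483647L)
  for (k in c(...)) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  # final multiplicative round so streams for consecutive indices do not get
  # consecutive generator seeds
  h <- (h * 69621 + 1) %% 2147483647
  as.integer(h %% 2147483629) + 1L
}
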