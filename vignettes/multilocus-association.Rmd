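---
title: "Multilocus case-control association tests: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus case-control association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(min2assoc)
```

## The problem

Given genotypes at $q$ diallelic SNPs in a genomic region for $n_1$ cases and
$n_0$ controls, we want a single test of the global null hypothesis that the
region is unassociated with disease. Single-marker tests lose power when the
causal variant is untyped or when its genetic mode (additive, dominant,
recessive) is unknown; multilocus tests recover power by exploiting linkage
disequilibrium (LD) among the typed SNPs, but their operating characteristics
depend strongly on how genotypes are coded and how the degrees of freedom are
controlled.

`min2assoc` implements a family of score-statistic tests on the minor-allele
count matrix $G \in \{0,1,2\}^{n \times q}$ with binary phenotype $Y$:

* **PChiP** — the principal-components-regression score test under additive
  coding;
* **PChiB** — a principal chi-squared test on a codominant empirical-Bayes
  score that adaptively exploits Hardy–Weinberg equilibrium (HWE);
* **SSUP** — the sum of squared prospective scores with a weighted
  chi-squared mixture null law;
* **Hotelling $T^2$** — the full-rank quadratic form;
* **GOLD** — the single-SNP oracle test on the known causal column
  (simulation benchmarking only);
* **Min2** — the permutation-calibrated minimum of the PChiP and PChiB
  p-values, designed to be robust to the unknown genetic mode.

## Score statistics

The additive prospective score is the logistic-regression score at the null:
$\tilde U_P = G^T(Y - \bar Y \mathbf 1)$ with covariance estimate
$\tilde V_P = \bar Y(1-\bar Y)\sum_i (G_i - \bar G)(G_i - \bar G)^T$.

Codominant coding replaces each count by the indicator pair
$m(g) = (I[g=1], I[g=2])$, so a SNP contributes two coordinates and no mode
is imposed. For SNP $k$, with pooled minor-allele frequency $\hat f_k$, the
HWE-implied expectation of $m$ is $(2\hat f_k(1-\hat f_k), \hat f_k^2)$; the
deviation $\tau_k = E_{HWE,\hat f_k}[m] - \bar m(g_k)$ measures how far the
pooled sample sits from HWE. The empirical-Bayes score for SNP $k$ is the
case sum

$$U_{B,k} = \sum_{i \in \text{cases}}
  \left[(m(G_{ik}) - E_{HWE,\hat f_k}[m])\,W_k +
        (m(G_{ik}) - \bar m(g_k))(I - W_k)\right],$$

with diagonal shrinkage weights
$W_k = \mathrm{diag}\!\left(\frac{s^2_j/n}{s^2_j/n + \tau_{jk}^2}\right)$
(indicator variances $s^2_j$ with denominator $n$). Near HWE ($\tau \approx
0$) the weight is close to one and the score centers at the HWE expectation,
which carries the retrospective-likelihood information that yields power
gains under recessive and dominant modes; under clear HWE violation the
weight collapses to zero and the score falls back to the prospective,
sample-mean-centered form, protecting the type-I error. Degenerate
coordinates with $s^2 = 0$ take weight 1 when $\tau = 0$ and 0 otherwise
(the continuous limits of the ratio).

## The covariance of the empirical-Bayes score

Under the null, conditioning on the pooled genotypes makes the case labels
exchangeable, which yields an exact decomposition

$$\mathrm{Var}(U_B) \;=\;
  \underbrace{\mathrm{Var}_{perm}\!\left(\textstyle\sum_{cases} x\right)}_{\approx\, V_P}
  \;+\; n_1^2\, \mathrm{Cov}(W\tau),$$

where $x$ denotes the codominant row vector. The first term is the
label-permutation covariance of the case sum and is estimated by the pooled
prospective covariance $V_P$. The second term is the sampling variability of
the weighted HWE deviation that shifts the blended score center; it is the
part a naive plug-in estimator misses. We evaluate it under the HWE regime
— where the retrospective component is active — by passing
$\tau^* \sim N(0, \hat\Sigma_\tau)$ through the weight-times-deviation map
$h_j(t) = t\,a_j/(a_j + t^2)$, $a_j = s_j^2/n$, where $\hat\Sigma_\tau$ is
the influence-function covariance of $\hat\tau$ (capturing both the plug-in
noise of $\hat f_k$ and cross-SNP LD). The map is integrated by
deterministic Gauss–Hermite quadrature (24 nodes), so `eb_covariance()` is a
pure function of the data. When HWE fails, the adaptive weights collapse and
the term overstates the small residual, so PChiB errs conservative — the
safe direction, and consistent with its observed behavior in the power
study. Supplying an explicit weight vector switches to the fixed-weight
closed form $V_P + n_1^2 W \hat\Sigma_\tau W$, whose $W = 0$ limit is
exactly $V_P$.

The combined matrix can acquire tiny negative tail eigenvalues (orders of
magnitude below the leading ones); it is projected onto the PSD cone by
clipping them, and an error is raised if the negative part ever exceeds 1%
of the largest eigenvalue.

Two contracts validate the estimator in the test suite: entrywise agreement
with the Monte-Carlo covariance of $U_B$ over 5000 null replicates of the
packaged panel (within 3 Monte-Carlo standard errors, up to the expected
multiplicity of 666 distinct entries), and empirical type-I error of PChiB
inside $[0.02, 0.08]$ at $\alpha = 0.05$ over 500 replicates with and
without inbreeding.

## Principal chi-squared tests and component selection

For a score $U$ with covariance $V$, eigendecompose
$V = \xi\,\mathrm{diag}(\lambda)\,\xi^T$ and form
$\mathrm{PChi} = \sum_{k \le s} (U\xi_k)^2/\lambda_k \sim \chi^2_s$ under
the null. The component count $s$ is the smallest number of top eigenvalues
explaining at least 85% of the total — computed over *retained* eigenvalues
only, after flooring $\lambda < 10^{-8}\lambda_{max}$ so that duplicated or
monomorphic columns cannot inflate the apparent variability. With $s$ equal
to the retained rank the statistic is Hotelling's $T^2 = U V^- U^T$. On the
additive prospective score this construction is algebraically identical to
the score test of the logistic regression of $Y$ on the top-$s$ principal
components of the centered genotype matrix (verified to $10^{-8}$ relative
tolerance in the tests). The 85% default follows standard
principal-components-regression practice (80–90% of genetic variability);
on null data simulated from the packaged NAT2 panel it selects 2 components
for PChiP and, modally, 5 for PChiB — the codominant expansion decorrelates
the coordinates, so PChiB absorbs more degrees of freedom, which is exactly
why it can lose power under an additive causal mode and why Min2 exists.
The 5-count sits on a knife edge: the cumulative eigenvalue fraction at five
components straddles 0.85 across null replicates (observed range about
0.84–0.87), so roughly a third of datasets select 6.

SSUP uses the same decomposition with eigenvalue weights,
$\mathrm{SSUP} = \sum_k U_k^2 = \sum_k \lambda_k (U a_k/\sqrt{\lambda_k})^2$;
its null law is the mixture $\sum_k \lambda_k \chi^2_1$, approximated by the
Liu–Tang–Zhang moment-matching method (mean, variance and skewness matched
to a shifted noncentral chi-squared; a Satterthwaite option is available).
For a single eigenvalue the approximation is exact.

## Min2 and its permutation calibration

Min2 observes $\min(p_{PChiP}, p_{PChiB})$. The minimum of two dependent
p-values is not uniform, so the p-value is calibrated by case-control label
permutation with the add-one estimator $(1 + \#\{Min2_{perm} \le
Min2_{obs}\})/(B+1)$, $B = 200$ by default. Every pooled-sample quantity in
both tests — allele frequencies, shrinkage weights, both covariance
estimates, hence eigenvalues, eigenvectors and the selected component counts
— depends on the pooled data only and is therefore invariant under label
permutation. Each permutation consequently reduces to recomputing case
column sums, a single matrix product over all permutations; holding the
eigenvectors fixed is exact here, not an approximation. The smallest
attainable p-value is $1/(B+1)$.

## The genotype simulator

The simulator is the package's reference implementation of the study
conditions, not a test fixture. A haplotype panel (strings over allele
symbols with frequencies; the packaged `nat2_panel()` carries 16 haplotypes
over 18 loci whose printed frequencies sum to 0.998 and are renormalized at
load) defines the generating law. Ordered haplotype pairs follow
$\phi_{HH'} = (1-F_{st}) f_H f_{H'} + \delta_{HH'} F_{st} f_H$: with
probability $F_{st}$ one haplotype is drawn and duplicated, otherwise two
independent draws — an exact $O(1)$ realization of the law. $F_{st} = 0$ is
HWE; $F_{st} > 0$ inflates homozygosity by the classical inbreeding
identity $P(\text{het}) = 2f(1-f)(1-F_{st})$, which the tests verify. Cases
reweight each ordered pair by
$R_{Aa}^{I(\text{Aa at causal})} R_{aa}^{I(\text{aa at causal})}$ and
renormalize; the same $F_{st}$-modified $\phi$ underlies both arms so each
inbreeding level pairs a null with its alternatives. Genetic modes map a
single odds ratio $\theta$ to $(R_{Aa}, R_{aa})$: additive
$(\theta, \theta^2)$ (multiplicative per allele on the odds scale),
dominant $(\theta, \theta)$, recessive $(1, \theta)$.

What the simulator emulates: realistic LD from a real gene's haplotype
structure, HWE and inbreeding deviations, mode-specific disease risk at a
single causal SNP. What it does not: population stratification, covariates,
genotyping error or missingness, rare variants, or multi-locus causal
architectures — so passing tests demonstrate correct operating
characteristics under single-causal-SNP regional LD, not robustness to
those complications.

GOLD, the benchmark, is the score test of the *true* generating model: the
causal column coded under its actual genetic mode. It is the oracle upper
reference in power tables and is unavailable in real analyses.

## Study runner, sizes and reproducibility

`run_study()` designates each SNP causal in turn and reports empirical
rejection fractions at $\alpha = 0.05$. The defaults are the study
conditions used for the package's own reference results: 1000 cases, 1000
controls, 500 replicates per cell, 200 permutations inside each Min2, the
85% selection threshold, and $F_{st} \in \{0, 0.5\log 2\}$. (Sources
describing this design vary between $0.5\log 2$ and $0.05\log 2$ for the
inbred setting; we adopt $0.5\log 2 \approx 0.347$, the value its tables
and figures state.) A cell's Monte-Carlo standard error is
$\sqrt{\hat p(1-\hat p)/500} \le 0.022$. Every replicate runs under a
substream seed derived from (master seed, causal index, replicate index)
through two multiplicative congruential mixing rounds — the second round
matters: without it consecutive replicates receive consecutive generator
seeds, which measurably distorted low-count rejection rates. Cells are
therefore individually reproducible and a fixed master seed gives
bit-identical tables.

Scenario handling: the multilocus tests can see all columns, all but the
causal column, or an explicit subset (e.g. tag SNPs, which must be supplied
as indices — the packaged panel does not identify which columns the named
tag SNPs occupy); GOLD always uses the causal column of the full data,
preserving its oracle semantics.

## Numerical choices and degenerate inputs

* Eigenvalue floor $10^{-8}\lambda_{max}$ for rank and the 85% denominator.
* Minor-allele ties at MAF 0.5 break to the lexicographically smaller
  symbol (radix order, locale-independent).
* Monomorphic SNPs are retained as zero-variance coordinates and removed by
  the eigenvalue floor, avoiding silent column renumbering; a monomorphic
  *causal* locus is an error for the simulator and GOLD.
* Missing genotypes are not modeled by the simulator; the VCF reader either
  drops samples with missing calls (default) or mean-imputes per SNP.
* Multi-allelic VCF sites are rejected rather than silently recoded.
* Permutation p-values use the add-one estimator, never zero.
* If the two p-values entering Min2 tie, the minimum is that value.

## Known limitations

* PChiB's component count is data-dependent near the 85% boundary (5 vs 6
  on the packaged panel), so its degrees of freedom — and marginally its
  power — vary across replicates.
* The weighted-deviation covariance term is evaluated under the HWE regime;
  at intermediate inbreeding levels PChiB is conservative rather than
  exactly calibrated.
* Covariate adjustment is out of scope; all scores condition on phenotype
  margins only.
* The mixture p-value for SSUP is a moment-matching approximation; extreme
  tail accuracy beyond roughly $10^{-4}$ should not be over-interpreted.
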