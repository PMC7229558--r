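Package: min2assoc
Title: Multilocus Case-Control Association Tests with Empirical-Bayes
    Principal Chi-Squared Statistics and the Min2 Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint association tests between a set of diallelic SNPs and a
    binary case-control phenotype. Implements the prospective principal
    chi-squared test on additively coded genotypes (PChiP), an
    empirical-Bayes codominant principal chi-squared test that adaptively
    exploits Hardy-Weinberg equilibrium (PChiB), the sum of squared scores
    test (SSUP), the single-SNP oracle score test (GOLD), Hotelling T2,
    and the permutation-calibrated minimum-p combination Min2. Also
    provides a haplotype-panel genotype simulator with an inbreeding
    (fixation-index) deviation from Hardy-Weinberg equilibrium and a
    simulation-study runner for empirical type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
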