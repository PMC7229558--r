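#' Write a genotype dataset as a dosage table
#'
#' Tab-separated text: a header row (`phenotype` then SNP ids), then one row
#' per sample holding the phenotype followed by the 0/1/2 minor-allele
#' counts. This is the interchange format written by the simulator and read
#' back by [read_dosage()].
#'
#' @param data a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(data, path) {
  stopifnot(inherits(data, "genotype_dataset"))
  tab <- data.frame(phenotype = data$phenotype, data$genotypes,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage table
#'
#' @param path a file written by [write_dosage()] (or any TSV with a
#'   `phenotype` column followed by 0/1/2 genotype columns).
#' @return A [genotype_dataset()].
#' @export
read_dosage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!"phenotype" %in% names(tab))
    stop("dosage table must contain a 'phenotype' column")
  ph <- tab$phenotype
  G <- as.matrix(tab[, setdiff(names(tab), "phenotype"), drop = FALSE])
  genotype_dataset(G, ph)
}

#' Read a genotype matrix from a VCF file
#'
#' Parses the GT field of a VCF into minor-allele counts. The minor allele
#' at each site is decided from the pooled sample allele frequency (dosages
#' are flipped where the ALT allele is the major one). Multi-allelic sites
#' are rejected. The VCF carries no phenotype, so case-control status is
#' supplied separately.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param phenotype binary vector, one entry per sample in the VCF.
#' @param na_action how to handle missing GT calls: `"drop"` removes
#'   samples with any missing call (the default), `"impute"` replaces a
#'   missing call with the rounded per-SNP mean dosage.
#' @return A [genotype_dataset()].
#' @export
read_vcf_genotypes <- function(path, phenotype,
                               na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic sites are not supported; split or filter them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles from diploid GT strings like 0/1, 1|1, ./.
  count_alt <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == ".")) return(NA_integer_)
      sum(as.integer(x) != 0L)
    }, integer(1))
  }
  D <- apply(gt, 1L, count_alt)                  # samples x sites
  if (is.null(dim(D))) D <- matrix(D, nrow = ncol(gt))
  snp_ids <- rownames(gt)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(D))
    stop("phenotype length must match the number of VCF samples")
  if (anyNA(D)) {
    if (na_action == "drop") {
      keep <- stats::complete.cases(D)
      D <- D[keep, , drop = FALSE]
      phenotype <- phenotype[keep]
    } else {
      for (k in seq_len(ncol(D))) {
        mis <- is.na(D[, k])
        if (any(mis)) D[mis, k] <- as.integer(round(mean(D[!mis, k])))
      }
    }
  }
  # flip sites where ALT is the pooled-sample major allele
  flip <- colMeans(D) / 2 > 0.5
  D[, flip] <- 2L - D[, flip]
  genotype_dataset(D, phenotype, snp_ids = snp_ids)
}
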