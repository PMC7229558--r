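#' Haplotype panels
#'
#' A haplotype panel is the generating distribution for the genotype
#' simulator: a set of haplotype strings (one allele symbol per locus) with
#' relative frequencies. Panels are diallelic: each locus may carry at most
#' two distinct symbols across the panel; loci with a single symbol are
#' flagged monomorphic. The minor allele at each polymorphic locus is the
#' symbol whose panel frequency is at most 0.5 (ties broken towards the
#' lexicographically smaller symbol).
#'
#' @param haplotypes character vector of haplotype strings, all the same
#'   length, one character per locus.
#' @param frequencies strictly positive numeric vector, one per haplotype.
#'   Renormalized at load to sum to one; the raw values are kept in the
#'   `raw_frequencies` field.
#' @return An object of class `hap_panel` with fields `haplotypes`,
#'   `frequencies` (normalized), `raw_frequencies`, `q` (locus count),
#'   `alleles` (q x haplotype indicator matrix is internal), `minor_allele`
#'   (per-locus symbol, `NA` at monomorphic loci), `maf_panel` (per-locus
#'   panel minor-allele frequency, 0 at monomorphic loci) and `monomorphic`
#'   (logical per locus).
#' @examples
#' p <- hap_panel(c("11", "12"), c(0.5, 0.5))
#' p$maf_panel
#' @export
hap_panel <- function(haplotypes, frequencies) {
  haplotypes <- as.character(haplotypes)
  frequencies <- as.numeric(frequencies)
  if (length(haplotypes) < 2L)
    stop("a haplotype panel needs at least 2 haplotypes")
  if (length(haplotypes) != length(frequencies))
    stop("haplotypes and frequencies must have equal length")
  lens <- nchar(haplotypes)
  if (length(unique(lens)) != 1L)
    stop("format error: haplotype strings have unequal lengths")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("haplotype frequencies must be strictly positive")
  q <- lens[[1L]]
  raw <- frequencies
  freq <- frequencies / sum(frequencies)

  # q x n_hap matrix of allele symbols
  sym <- do.call(cbind, strsplit(haplotypes, "", fixed = TRUE))
  minor <- character(q)
  maf <- numeric(q)
  mono <- logical(q)
  hap_minor <- matrix(0L, nrow = length(haplotypes), ncol = q)
  for (k in seq_len(q)) {
    alleles <- sort(unique(sym[k, ]), method = "radix")  # locale-independent
    if (length(alleles) > 2L)
      stop(sprintf("diallelic violation: locus %d carries %d alleles",
                   k, length(alleles)))
    if (length(alleles) == 1L) {
      mono[k] <- TRUE
      minor[k] <- NA_character_
      maf[k] <- 0
      next
    }
    f1 <- sum(freq[sym[k, ] == alleles[[1L]]])
    # minor = symbol with frequency <= 0.5, lexicographic tie-break
    if (f1 <= 0.5) {
      minor[k] <- alleles[[1L]]
      maf[k] <- f1
    } else {
      minor[k] <- alleles[[2L]]
      maf[k] <- 1 - f1
    }
    hap_minor[, k] <- as.integer(sym[k, ] == minor[k])
  }
  structure(
    list(haplotypes = haplotypes, frequencies = freq, raw_frequencies = raw,
         q = q, minor_allele = minor, maf_panel = maf, monomorphic = mono,
         hap_minor = hap_minor),
    class = "hap_panel")
}

#' Load a haplotype panel from a two-column table
#'
#' Reads a whitespace- or tab-delimited file with one haplotype string and
#' one frequency per row (no header) and builds a [hap_panel()].
#'
#' @param path path to the panel file.
#' @return A `hap_panel` object.
#' @seealso [nat2_panel()] for the packaged NAT2 panel.
#' @export
load_panel <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = c("character", "numeric"),
                           col.names = c("haplotype", "frequency"))
  if (nrow(tab) < 2L) stop("panel file must contain at least 2 rows")
  hap_panel(tab$haplotype, tab$frequency)
}

#' The NAT2 haplotype panel
#'
#' The packaged 18-locus, 16-haplotype panel for the NAT2 gene region
#' (HapMap CEU; SNPs with MAF > 0.05). Its printed frequencies sum to
#' 0.998 and are renormalized at load.
#'
#' @return A `hap_panel` with `q = 18` loci.
#' @export
nat2_panel <- function() {
  load_panel(system.file("extdata", "nat2_haplotypes.tsv",
                         package = "min2assoc", mustWork = TRUE))
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes x %d loci (%d monomorphic)\n",
              length(x$haplotypes), x$q, sum(x$monomorphic)))
  cat("Panel MAF range:", sprintf("%.3f", min(x$maf_panel[!x$monomorphic])),
      "-", sprintf("%.3f", max(x$maf_panel)), "\n")
  invisible(x)
}
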