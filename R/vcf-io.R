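#' Read a biallelic SNP genotype matrix from VCF
#'
#' Reads GT fields via \pkg{vcfR}, keeps biallelic SNP records only
#' (multi-allelic sites and indels are dropped with a logged count), and maps
#' genotypes 0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA. Haploid GT strings
#' ("0", "1", ".") are read as pseudo-haploid calls; a file whose genotypes
#' are all haploid yields a pseudo-haploid matrix.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param pops Optional `population_map`; when given, the matrix is restricted
#'   to mapped samples and every mapped sample must be present in the header.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, pops = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (!n_in) stopf("no records in %s", path)
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop) log_msg("read_vcf: dropped %d multi-allelic/indel record(s)", n_drop)
  if (!any(keep)) stopf("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  vcf_samples <- colnames(gt)
  if (!is.null(pops)) {
    want <- names(pops$assignments)
    missing_s <- setdiff(want, vcf_samples)
    if (length(missing_s))
      stopf("sample(s) in population map absent from VCF: %s",
            paste(missing_s, collapse = ", "))
    gt <- gt[, want, drop = FALSE]
  }

  gt_chr <- gsub("\\|", "/", as.character(gt))
  calls <- rep(NA_integer_, length(gt_chr))
  haploid <- gt_chr %in% c("0", "1")
  calls[gt_chr == "0/0"] <- 0L
  calls[gt_chr %in% c("0/1", "1/0")] <- 1L
  calls[gt_chr == "1/1"] <- 2L
  calls[gt_chr == "0"] <- 0L
  calls[gt_chr == "1"] <- 2L
  dim(calls) <- dim(gt)
  colnames(calls) <- colnames(gt)

  called <- !is.na(as.vector(gt)) & !(gt_chr %in% c(".", "./."))
  ploidy <- if (any(called) && all(haploid[called])) "pseudo-haploid" else "diploid"

  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  dup <- duplicated(loci[, c("chrom", "pos")])
  if (any(dup)) {
    log_msg("read_vcf: dropped %d duplicate position(s)", sum(dup))
    loci <- loci[!dup, , drop = FALSE]
    calls <- calls[!dup, , drop = FALSE]
  }
  genotype_matrix(loci, colnames(calls), calls, ploidy = ploidy)
}

#' Write a genotype matrix as plain-text VCF 4.2 (GT only)
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bisonmix",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  if (g$ploidy == "diploid") {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    miss <- "./."
  } else {
    code <- c(`0` = "0", `2` = "1")
    miss <- "."
  }
  gt <- matrix(miss, nrow(g$calls), ncol(g$calls))
  ok <- !is.na(g$calls)
  gt[ok] <- code[as.character(g$calls[ok])]
  body <- paste(g$loci$chrom, g$loci$pos, ".", g$loci$ref, g$loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
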