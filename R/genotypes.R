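#' Biallelic genotype matrix for sparse ancient-DNA data
#'
#' The central data container: an loci x samples matrix of alternate-allele
#' counts over \{0, 1, 2, NA\} (diploid) or \{0, 2, NA\} (pseudo-haploid, where
#' a single sampled allele is stored as 0 or 2 and NA marks a missing call).
#' Loci must be biallelic SNPs, sorted and unique by (chrom, pos).
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt` (single bases, distinct).
#' @param samples Character vector of sample identifiers (unique).
#' @param calls Integer matrix, `nrow(loci)` x `length(samples)`, values in
#'   \{0, 1, 2, NA\}.
#' @param ploidy `"diploid"` or `"pseudo-haploid"`. Pseudo-haploid matrices
#'   may not contain the value 1.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, samples,
                            calls,
                            ploidy = c("diploid", "pseudo-haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stopf("duplicate sample identifiers")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(loci) || ncol(calls) != length(samples))
    stopf("calls must be %d x %d", nrow(loci), length(samples))
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stopf("calls must lie in {0, 1, 2, NA}")
  if (!all(nchar(loci$ref) == 1L & nchar(loci$alt) == 1L & loci$ref != loci$alt))
    stopf("every locus must be biallelic: single-base ref and alt, distinct")
  ord <- order(loci$chrom, loci$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    loci <- loci[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
  }
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stopf("duplicate loci (chrom, pos) are not allowed")
  if (ploidy == "pseudo-haploid" && any(calls == 1L, na.rm = TRUE))
    stopf("pseudo-haploid matrix contains heterozygous calls")
  rownames(loci) <- NULL
  dimnames(calls) <- list(NULL, samples)
  structure(list(loci = loci, samples = samples, calls = calls,
                 ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples (%s)\n",
              n_loci(x), length(x$samples), x$ploidy))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci in a genotype matrix
#' @param g A `genotype_matrix`.
#' @export
n_loci <- function(g) nrow(g$loci)

#' Sample-to-population assignments plus role labels
#'
#' Populations group samples; roles name the positions populations take in the
#' admixture graph under study. The core vocabulary is `HYBRID` (the admixed
#' lineage, wisent/CladeX), `SOURCE_B` (steppe bison), `SOURCE_C`
#' (aurochs/cattle), `SISTER_A` (sister taxon of SOURCE_B, American bison) and
#' `OUTGROUP` (sheep). Additional roles (e.g. `HYBRID2` for a second hybrid
#' lineage) are accepted.
#'
#' @param assignments Named character vector (names = samples, values =
#'   population labels) or a two-column data.frame (sample, population).
#' @param roles Named character vector or list mapping role labels to
#'   population labels.
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignments, roles = character()) {
  if (is.data.frame(assignments)) {
    stopifnot(ncol(assignments) >= 2L)
    a <- as.character(assignments[[2L]])
    names(a) <- as.character(assignments[[1L]])
    assignments <- a
  }
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stopf("assignments must be uniquely named by sample")
  roles <- unlist(roles)
  roles <- stats::setNames(as.character(roles), names(roles))
  pops <- unique(unname(assignments))
  for (r in names(roles)) {
    if (!nzchar(roles[[r]]) || !(roles[[r]] %in% pops))
      stopf("role %s maps to population '%s' with no assigned samples",
            r, roles[[r]])
  }
  structure(list(assignments = assignments, roles = roles),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("population_map: %d samples, %d populations, %d roles\n",
              length(x$assignments), length(unique(x$assignments)),
              length(x$roles)))
  for (r in names(x$roles)) cat(sprintf("  %s -> %s\n", r, x$roles[[r]]))
  invisible(x)
}

#' Read a sample-to-population map from a two-column TSV
#'
#' @param path TSV with columns sample, population (no header required; a
#'   header line `sample<TAB>population` is tolerated).
#' @param roles Named character vector mapping roles to populations.
#' @export
read_population_map <- function(path, roles = character()) {
  if (!file.exists(path)) stopf("population map not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df$sample[1L]), "sample"))
    df <- df[-1L, , drop = FALSE]
  population_map(df, roles)
}

#' Write a population map to TSV (sample, population)
#' @param pops A `population_map`.
#' @param path Output path.
#' @export
write_population_map <- function(pops, path) {
  utils::write.table(
    data.frame(sample = names(pops$assignments),
               population = unname(pops$assignments)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# samples belonging to the population filling `role`
role_samples <- function(g, pops, role) {
  if (!role %in% names(pops$roles)) stopf("role %s is not mapped", role)
  pop <- pops$roles[[role]]
  s <- names(pops$assignments)[pops$assignments == pop]
  s <- intersect(s, g$samples)
  if (!length(s)) stopf("no samples of role %s (population %s) in matrix",
                        role, pop)
  s
}

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Replaces every heterozygous call by a single sampled allele (0 or 2 with
#' probability 1/2 each), the standard representation for low-coverage ancient
#' DNA. The random stream is a function of `seed` and the (locus, sample) cell
#' index only, so the result is reproducible and independent of how many
#' heterozygotes the matrix contains.
#'
#' @param g A diploid `genotype_matrix`.
#' @param seed Integer seed.
#' @return A pseudo-haploid `genotype_matrix`.
#' @export
haploidize <- function(g, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$ploidy == "pseudo-haploid") {
    warnf("matrix is already pseudo-haploid; returning unchanged")
    return(g)
  }
  u <- with_seed(seed, matrix(stats::runif(length(g$calls)),
                              nrow = nrow(g$calls)))
  calls <- g$calls
  het <- which(!is.na(calls) & calls == 1L)
  calls[het] <- ifelse(u[het] < 0.5, 0L, 2L)
  genotype_matrix(g$loci, g$samples, calls, ploidy = "pseudo-haploid")
}

#' Per-population alternate-allele frequencies
#'
#' For each locus and population: frequency = (alternate alleles observed) /
#' (total non-missing allele observations). Diploid calls contribute two
#' alleles, pseudo-haploid calls one. `NA` where a population has no data.
#'
#' @param g A `genotype_matrix`.
#' @param pops A `population_map`.
#' @return A `freq_table`: list with `freq` and `n_obs` matrices
#'   (loci x populations) and the locus table.
#' @export
allele_freqs <- function(g, pops) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(pops, "population_map"))
  pl <- unique(unname(pops$assignments))
  per_call <- if (g$ploidy == "diploid") 2L else 1L
  alt_per_call <- function(x) if (per_call == 2L) x else x / 2L
  freq <- matrix(NA_real_, n_loci(g), length(pl), dimnames = list(NULL, pl))
  nobs <- matrix(0L, n_loci(g), length(pl), dimnames = list(NULL, pl))
  for (p in pl) {
    s <- intersect(names(pops$assignments)[pops$assignments == p], g$samples)
    if (!length(s)) next
    sub <- g$calls[, s, drop = FALSE]
    k <- rowSums(!is.na(sub)) * per_call
    alt <- rowSums(alt_per_call(sub), na.rm = TRUE)
    freq[, p] <- ifelse(k > 0L, alt / k, NA_real_)
    nobs[, p] <- as.integer(k)
  }
  structure(list(freq = freq, n_obs = nobs, loci = g$loci,
                 populations = pl),
            class = "freq_table")
}

# resolve a vector of role-or-population labels to freq_table columns
resolve_pops <- function(labels, freqs, pops = NULL) {
  vapply(labels, function(l) {
    if (l %in% colnames(freqs$freq)) return(l)
    if (!is.null(pops) && l %in% names(pops$roles)) {
      p <- pops$roles[[l]]
      if (p %in% colnames(freqs$freq)) return(p)
    }
    stopf("quartet label '%s' is neither a population nor a mapped role", l)
  }, character(1L))
}
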