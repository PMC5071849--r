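#' Outgroup-polarized site-pattern counts for a taxon quartet
#'
#' For an ordered quartet of roles (P1, P2, P3, Outgroup), draws one
#' representative allele per population per locus (seeded; the draw is keyed
#' to the population, not the quartet position, so relabelling roles permutes
#' patterns exactly), polarizes by the outgroup allele (ancestral state A) and
#' counts the three informative two-derived patterns:
#' \describe{
#'   \item{BBAA}{P1 and P2 derived}
#'   \item{ABBA}{P2 and P3 derived}
#'   \item{BABA}{P1 and P3 derived}
#' }
#' Loci missing in any role, or where the outgroup is polymorphic across its
#' samples, are skipped; non-informative loci (no derived allele, a singleton
#' derived allele, or all three ingroups derived) are excluded from the three
#' cells but tallied.
#'
#' @param g A `genotype_matrix`.
#' @param pops A `population_map` covering the four roles.
#' @param quartet Character(4): role or population labels (P1, P2, P3, O).
#' @param seed Integer seed for the representative-allele draws.
#' @return An object of class `site_pattern_counts` with fields `n_BBAA`,
#'   `n_ABBA`, `n_BABA`, `n_total_informative`, `taxon_order` and skip tallies.
#' @export
site_pattern_counts <- function(g, pops, quartet = c("HYBRID", "SOURCE_B",
                                                     "SOURCE_C", "OUTGROUP"),
                                seed = 1L) {
  stopifnot(length(quartet) == 4L)
  fr <- allele_freqs(g, pops)
  cols <- resolve_pops(quartet, fr, pops)
  f <- fr$freq[, cols, drop = FALSE]

  # one representative allele per population per locus: derived iff u < freq.
  # u is generated per population in sorted-population order so the draw for a
  # given population does not depend on its quartet position.
  pops_used <- sort(unique(cols))
  u_all <- with_seed(seed, {
    m <- matrix(stats::runif(n_loci(g) * length(pops_used)), n_loci(g))
    colnames(m) <- pops_used
    m
  })
  u <- u_all[, cols, drop = FALSE]

  callable <- !is.na(f[, 1L]) & !is.na(f[, 2L]) & !is.na(f[, 3L]) & !is.na(f[, 4L])
  out_poly <- callable & f[, 4L] > 0 & f[, 4L] < 1
  use <- callable & !out_poly
  n_skip_missing <- sum(!callable)
  n_skip_poly <- sum(out_poly)

  # representative alt-allele indicator, then polarize by the outgroup allele
  rep_alt <- u[use, 1:3, drop = FALSE] < f[use, 1:3, drop = FALSE]
  out_alt <- f[use, 4L] == 1
  derived <- sweep(rep_alt, 1L, out_alt, FUN = "!=")
  nd <- rowSums(derived)
  bbaa <- nd == 2L & derived[, 1L] & derived[, 2L]
  abba <- nd == 2L & derived[, 2L] & derived[, 3L]
  baba <- nd == 2L & derived[, 1L] & derived[, 3L]
  n_info <- sum(nd == 2L)
  if (n_info == 0L)
    stopf("zero informative loci for quartet (%s)", paste(quartet, collapse = ", "))

  structure(list(n_BBAA = sum(bbaa), n_ABBA = sum(abba), n_BABA = sum(baba),
                 n_total_informative = n_info,
                 taxon_order = quartet,
                 n_skipped_missing = n_skip_missing,
                 n_skipped_polymorphic_outgroup = n_skip_poly,
                 n_noninformative = sum(use) - n_info),
            class = "site_pattern_counts")
}

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat(sprintf("site_pattern_counts (%s)\n", paste(x$taxon_order, collapse = ", ")))
  cat(sprintf("  BBAA=%d ABBA=%d BABA=%d (informative: %d)\n",
              x$n_BBAA, x$n_ABBA, x$n_BABA, x$n_total_informative))
  cat(sprintf("  skipped: %d missing, %d polymorphic outgroup; %d non-informative\n",
              x$n_skipped_missing, x$n_skipped_polymorphic_outgroup,
              x$n_noninformative))
  invisible(x)
}

# counts as a named triple in canonical order
pattern_vector <- function(x) {
  c(BBAA = x$n_BBAA, ABBA = x$n_ABBA, BABA = x$n_BABA)
}
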