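# f4 statistics and the f4-ratio estimator of admixture proportions:
# the fraction alpha of the hybrid lineage's nuclear ancestry attributable to
# SOURCE_B (steppe bison), with 1 - alpha from SOURCE_C (aurochs/cattle).

#' f4 statistic
#'
#' Mean over usable loci of (a - o)(x - c) for the quadruple (A, O; X, C) of
#' per-locus population allele frequencies. Loci missing in any of the four
#' roles are skipped.
#'
#' @param freqs A `freq_table`.
#' @param quadruple Character(4) population or role labels (A, O, X, C).
#' @param pops Optional `population_map` to resolve roles.
#' @return The f4 value with attribute `n_used`.
#' @export
f4 <- function(freqs, quadruple, pops = NULL) {
  stopifnot(inherits(freqs, "freq_table"), length(quadruple) == 4L)
  cols <- resolve_pops(quadruple, freqs, pops)
  f <- freqs$freq[, cols, drop = FALSE]
  ok <- stats::complete.cases(f)
  if (!any(ok)) stopf("f4: no locus with data in all four roles")
  v <- (f[ok, 1L] - f[ok, 2L]) * (f[ok, 3L] - f[ok, 4L])
  structure(mean(v), n_used = sum(ok))
}

#' Admixture proportion via the f4 ratio
#'
#' Estimates the proportion alpha of `HYBRID` ancestry derived from
#' `SOURCE_B` as
#' \deqn{\alpha = f4(SISTER\_A, OUTGROUP; HYBRID, SOURCE\_C) /
#'       f4(SISTER\_A, OUTGROUP; SOURCE\_B, SOURCE\_C)}
#' Both f4 values are computed over the same locus set (loci with data in all
#' five roles), and the standard error comes from a weighted delete-one block
#' jackknife where the full ratio is recomputed for each deleted block
#' (correct for a nonlinear functional). Estimates outside [0, 1] are
#' returned unclamped with a warning flag.
#'
#' @param g A `genotype_matrix`.
#' @param pops A `population_map` covering HYBRID, SOURCE_B, SOURCE_C,
#'   SISTER_A, OUTGROUP (the HYBRID role can be overridden to e.g. HYBRID2).
#' @param block_size Jackknife block size in loci (default 200).
#' @param hybrid_role Role label of the admixed lineage (default "HYBRID").
#' @return An `ancestry_estimate`: alpha, one_minus_alpha, SE, numerator_f4,
#'   denominator_f4, n_used, n_blocks, roles_used, flags.
#' @export
f4_ratio <- function(g, pops, block_size = 200L, hybrid_role = "HYBRID") {
  freqs <- allele_freqs(g, pops)
  roles <- c(SISTER_A = "SISTER_A", OUTGROUP = "OUTGROUP",
             HYBRID = hybrid_role, SOURCE_B = "SOURCE_B",
             SOURCE_C = "SOURCE_C")
  cols <- resolve_pops(unname(roles), freqs, pops)
  f <- freqs$freq[, cols, drop = FALSE]
  ok <- stats::complete.cases(f)
  if (!any(ok)) stopf("f4_ratio: no locus with data in all five roles")
  a <- f[, 1L]; o <- f[, 2L]; h <- f[, 3L]; b <- f[, 4L]; cc <- f[, 5L]
  num <- (a - o) * (h - cc)
  den <- (a - o) * (b - cc)
  num[!ok] <- 0; den[!ok] <- 0
  den_tot <- sum(den)
  if (den_tot == 0) stopf("f4_ratio: zero denominator f4")
  alpha <- sum(num) / den_tot

  blk <- block_index(length(num), block_size)
  num_b <- tapply(num, blk, sum)
  den_b <- tapply(den, blk, sum)
  m_b <- tapply(ok, blk, sum)
  keep <- m_b > 0L & (den_tot - den_b) != 0
  theta_del <- (sum(num) - num_b[keep]) / (den_tot - den_b[keep])
  SE <- weighted_jackknife_se(alpha, theta_del, m_b[keep])

  # flag an unstable ratio: denominator f4 not significantly non-zero
  den_hat <- den_tot / sum(ok)
  den_del <- (den_tot - den_b[keep]) / (sum(ok) - m_b[keep])
  den_se <- weighted_jackknife_se(den_hat, den_del, m_b[keep])
  den_unstable <- !is.na(den_se) && den_se > 0 && abs(den_hat / den_se) < 3
  if (den_unstable)
    warnf("f4_ratio: denominator f4 is not significantly non-zero; ratio unstable")
  out_of_range <- alpha < 0 || alpha > 1
  if (out_of_range)
    warnf("f4_ratio: alpha = %.4f outside [0, 1]; reported unclamped", alpha)

  structure(list(alpha = alpha, one_minus_alpha = 1 - alpha, SE = SE,
                 numerator_f4 = sum(num) / sum(ok),
                 denominator_f4 = den_hat,
                 n_used = sum(ok), n_blocks = sum(keep),
                 roles_used = stats::setNames(unname(cols), names(roles)),
                 hybrid_role = hybrid_role,
                 out_of_range = out_of_range,
                 denominator_unstable = den_unstable),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf("f4-ratio ancestry for %s: %.1f%% SOURCE_B / %.1f%% SOURCE_C (SE %.1f%%)\n",
              x$hybrid_role, 100 * x$alpha, 100 * x$one_minus_alpha,
              100 * x$SE))
  cat(sprintf("  f4 num = %.6g, den = %.6g over %d loci (%d blocks)\n",
              x$numerator_f4, x$denominator_f4, x$n_used, x$n_blocks))
  invisible(x)
}

#' Tabulate ancestry estimates per lineage
#'
#' Formats one row per hybrid lineage with steppe/aurochs percentages (one
#' decimal place) and jackknife SEs.
#'
#' @param estimates A list of `ancestry_estimate` objects (optionally named by
#'   lineage).
#' @return data.frame with columns lineage, steppe_pct, aurochs_pct, se_pct,
#'   label.
#' @export
ancestry_report <- function(estimates) {
  if (inherits(estimates, "ancestry_estimate")) estimates <- list(estimates)
  if (!length(estimates)) stopf("ancestry_report: no estimates given")
  nm <- names(estimates) %||% rep(NA_character_, length(estimates))
  rows <- lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    stopifnot(inherits(e, "ancestry_estimate"))
    lineage <- if (!is.na(nm[i]) && nzchar(nm[i])) nm[i] else e$hybrid_role
    sp <- round(100 * e$alpha, 1L)
    ap <- round(100 * e$one_minus_alpha, 1L)
    data.frame(lineage = lineage, steppe_pct = sp, aurochs_pct = ap,
               se_pct = round(100 * e$SE, 1L),
               label = sprintf("%.1f%% steppe / %.1f%% aurochs", sp, ap),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
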