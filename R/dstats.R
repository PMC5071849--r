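# D-statistics with weighted block-jackknife standard errors, and the
# three-topology ranking used to choose the most parsimonious arrangement of
# three ingroup populations against a fixed outgroup.

# contiguous block index per locus
block_index <- function(n, block_size) {
  stopifnot(is_count(block_size), block_size >= 1L)
  ((seq_len(n) - 1L) %/% block_size) + 1L
}

# Weighted delete-one-block jackknife (Busing et al. 1999), the convention of
# standard D-statistic software: blocks are weighted by their number of
# informative loci. theta_hat: full estimate; theta_del: per-block delete-one
# estimates; m: per-block weights; n = sum(m).
weighted_jackknife_se <- function(theta_hat, theta_del, m) {
  g <- length(theta_del)
  n <- sum(m)
  if (g < 2L) return(NA_real_)
  h <- n / m
  theta_J <- g * theta_hat - sum((1 - m / n) * theta_del)
  tau <- h * theta_hat - (h - 1) * theta_del
  sqrt(sum((tau - theta_J)^2 / (h - 1)) / g)
}

#' ABBA-BABA D-statistic with block-jackknife standard error
#'
#' For a quartet (W, X, Y, Z) with per-locus population allele frequencies
#' (w, x, y, z), computes
#' \deqn{D = \sum_i (x_i - w_i)(y_i - z_i) / \sum_i (w_i + x_i - 2 w_i x_i)(y_i + z_i - 2 y_i z_i)}
#' so that with Z the outgroup, D > 0 indicates excess allele sharing between
#' X and Y (ABBA patterns) and D < 0 excess sharing between W and Y (BABA);
#' in count form D = (nABBA - nBABA) / (nABBA + nBABA). D = 0 is expected
#' under the unrooted topology ((W,X),(Y,Z)) without gene flow. The standard
#' error comes from a weighted delete-one block jackknife over contiguous
#' blocks of `block_size` loci (weights proportional to per-block informative
#' loci), and Z-score = D/SE.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param quartet Character(4) of population or role labels (W, X, Y, Z).
#' @param block_size Loci per jackknife block (default 200).
#' @param pops Optional `population_map` for resolving role labels.
#' @param z_crit Significance convention on |Z| (default 3, i.e. three
#'   standard errors).
#' @return A `d_stat` object: quartet, populations, D, SE, Z, n_blocks,
#'   n_informative, significant.
#' @export
d_statistic <- function(freqs, quartet, block_size = 200L, pops = NULL,
                        z_crit = 3) {
  stopifnot(inherits(freqs, "freq_table"), length(quartet) == 4L)
  cols <- resolve_pops(quartet, freqs, pops)
  f <- freqs$freq[, cols, drop = FALSE]
  w <- f[, 1L]; x <- f[, 2L]; y <- f[, 3L]; z <- f[, 4L]
  ok <- !is.na(w) & !is.na(x) & !is.na(y) & !is.na(z)
  if (!any(ok)) stopf("no locus with data in all four roles (%s)",
                      paste(quartet, collapse = ", "))
  num <- (x - w) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  num[!ok] <- 0; den[!ok] <- 0

  den_tot <- sum(den)
  if (den_tot == 0)
    stopf("D undefined: zero denominator for quartet (%s)",
          paste(quartet, collapse = ", "))
  D <- sum(num) / den_tot

  blk <- block_index(length(w), block_size)
  num_b <- tapply(num, blk, sum)
  den_b <- tapply(den, blk, sum)
  m_b <- tapply(ok, blk, sum)
  keep <- m_b > 0L & (sum(den) - den_b) != 0
  num_b <- num_b[keep]; den_b <- den_b[keep]; m_b <- m_b[keep]
  theta_del <- (sum(num) - num_b) / (den_tot - den_b)
  SE <- weighted_jackknife_se(D, theta_del, m_b)
  Z <- if (is.na(SE) || SE == 0) NA_real_ else D / SE
  structure(list(quartet = quartet, populations = unname(cols),
                 D = D, SE = SE, Z = Z,
                 n_blocks = length(theta_del),
                 n_informative = sum(ok),
                 significant = !is.na(Z) && abs(Z) > z_crit,
                 z_crit = z_crit),
            class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("D(%s) = %.4f  SE = %.4f  Z = %s  [%d loci, %d blocks]%s\n",
              paste(x$quartet, collapse = ","), x$D, x$SE,
              ifelse(is.na(x$Z), "NA", sprintf("%.2f", x$Z)),
              x$n_informative, x$n_blocks,
              if (isTRUE(x$significant)) "  *" else ""))
  invisible(x)
}

#' Rank the three unrooted topologies of three ingroup populations
#'
#' For ingroup populations (P, Q, R) and a fixed outgroup, the arrangement
#' ((P,Q),R) predicts D(P, Q; R, Outgroup) = 0 without gene flow. All three
#' arrangements are evaluated; the most parsimonious is the one whose D is
#' closest to 0, and arrangements with |Z| above `z_crit` are flagged as
#' rejected by the data.
#'
#' @param g A `genotype_matrix`.
#' @param pops A `population_map` with `OUTGROUP` and the three ingroup roles.
#' @param block_size Jackknife block size in loci.
#' @param ingroup Character(3) of ingroup role/population labels.
#' @param z_crit Significance threshold on |Z| (default 3).
#' @return A `topology_ranking`: data.frame of the three tests plus the index
#'   of the best arrangement.
#' @export
rank_topologies <- function(g, pops, block_size = 200L,
                            ingroup = c("HYBRID", "SOURCE_B", "SISTER_A"),
                            z_crit = 3) {
  stopifnot(length(ingroup) == 3L)
  freqs <- allele_freqs(g, pops)
  ing <- sort(ingroup)  # canonical order: ranking invariant to input order
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  res <- lapply(pairs, function(pr) {
    third <- setdiff(1:3, pr)
    d_statistic(freqs, c(ing[pr], ing[third], "OUTGROUP"),
                block_size = block_size, pops = pops, z_crit = z_crit)
  })
  tab <- data.frame(
    arrangement = vapply(pairs, function(pr)
      sprintf("((%s,%s),%s)", ing[pr[1L]], ing[pr[2L]],
              ing[setdiff(1:3, pr)]), character(1L)),
    D = vapply(res, `[[`, numeric(1L), "D"),
    SE = vapply(res, `[[`, numeric(1L), "SE"),
    Z = vapply(res, `[[`, numeric(1L), "Z"),
    n_informative = vapply(res, `[[`, integer(1L), "n_informative"),
    n_blocks = vapply(res, `[[`, integer(1L), "n_blocks"),
    significant = vapply(res, `[[`, logical(1L), "significant"),
    stringsAsFactors = FALSE)
  structure(list(results = tab, tests = res,
                 best = which.min(abs(tab$D)), z_crit = z_crit),
            class = "topology_ranking")
}

#' @export
print.topology_ranking <- function(x, ...) {
  tab <- x$results
  tab$best <- ifelse(seq_len(nrow(tab)) == x$best, "<=", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a D-statistic report table as TSV
#'
#' One row per quartet: D, SE, Z, n_blocks, n_informative, significant.
#' @param x A `topology_ranking` or list of `d_stat` objects.
#' @param path Output TSV path.
#' @export
write_dstat_report <- function(x, path) {
  tab <- if (inherits(x, "topology_ranking")) x$results else {
    do.call(rbind, lapply(x, function(d) data.frame(
      arrangement = paste(d$quartet, collapse = ","),
      D = d$D, SE = d$SE, Z = d$Z,
      n_informative = d$n_informative, n_blocks = d$n_blocks,
      significant = d$significant, stringsAsFactors = FALSE)))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
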