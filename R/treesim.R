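# Generative model for site-pattern counts: a quartet species tree with
# internal branch length t (coalescent units) makes its concordant pattern
# occur with probability 1 - (2/3)exp(-t) and each discordant pattern with
# probability (1/3)exp(-t) (incomplete lineage sorting). Counts for an
# admixed lineage are a linear combination of draws from two such trees.

PATTERN_CLASSES <- c("BBAA", "ABBA", "BABA")

#' Quartet topology model for site-pattern probabilities
#'
#' @param label Model label (e.g. "X1", "X2").
#' @param concordant_class Which pattern the topology makes concordant:
#'   "BBAA", "ABBA" or "BABA".
#' @param t Internal branch length in coalescent units (>= 0).
#' @return A `topology_model`.
#' @export
topology_model <- function(label, concordant_class, t) {
  concordant_class <- match.arg(concordant_class, PATTERN_CLASSES)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stopf("internal branch length t must be a non-negative number")
  structure(list(label = label, concordant_class = concordant_class, t = t),
            class = "topology_model")
}

#' Site-pattern probabilities under a quartet topology
#'
#' The concordant class has probability 1 - (2/3)exp(-t); each discordant
#' class has (1/3)exp(-t). At t = 0 (star tree) all three are 1/3; as t grows
#' the concordant probability tends to 1.
#'
#' @param model A `topology_model`.
#' @return Named numeric(3) over (BBAA, ABBA, BABA), summing to 1.
#' @export
pattern_probs <- function(model) {
  stopifnot(inherits(model, "topology_model"))
  e <- exp(-model$t)
  p <- stats::setNames(rep(e / 3, 3L), PATTERN_CLASSES)
  p[model$concordant_class] <- 1 - 2 * e / 3
  p
}

# vectorized probability triples for many t at once
pattern_probs_t <- function(t, concordant_class) {
  e <- exp(-t)
  p <- matrix(e / 3, length(t), 3L, dimnames = list(NULL, PATTERN_CLASSES))
  p[, concordant_class] <- 1 - 2 * e / 3
  p
}

# vectorized multinomial sampler (binomial chain); rows of P are prob triples
rmultinom_rows <- function(n, P) {
  c1 <- stats::rbinom(length(n), n, P[, 1L])
  rem <- n - c1
  p2 <- ifelse(P[, 1L] >= 1, 0, pmin(pmax(P[, 2L] / (1 - P[, 1L]), 0), 1))
  c2 <- stats::rbinom(length(n), rem, p2)
  cbind(c1, c2, rem - c2, deparse.level = 0L)
}

#' Simulate site-pattern counts under a two-topology mixture
#'
#' Draws `round(alpha * n_loci)` loci from the multinomial implied by `m1`
#' and the remainder from `m2` (a binomial split of the locus count is
#' available via `split = "binomial"`); total is conserved at `n_loci`.
#'
#' @param m1,m2 `topology_model` objects.
#' @param n_loci Number of loci to simulate.
#' @param alpha Mixing proportion in [0, 1] (fraction of loci from `m1`).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param split `"round"` (deterministic split, default) or `"binomial"`.
#' @return A `site_pattern_counts` object.
#' @export
simulate_counts <- function(m1, m2, n_loci, alpha, seed = NULL,
                            split = c("round", "binomial")) {
  split <- match.arg(split)
  stopifnot(inherits(m1, "topology_model"), inherits(m2, "topology_model"))
  if (!is_count(n_loci) || n_loci < 1) stopf("n_loci must be a positive integer")
  if (!is.numeric(alpha) || is.na(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1]")
  cnt <- with_seed(seed, {
    n1 <- if (split == "round") as.integer(round(alpha * n_loci))
          else stats::rbinom(1L, as.integer(n_loci), alpha)
    c1 <- drop(stats::rmultinom(1L, n1, pattern_probs(m1)))
    c2 <- drop(stats::rmultinom(1L, n_loci - n1, pattern_probs(m2)))
    c1 + c2
  })
  stopifnot(sum(cnt) == n_loci)
  structure(list(n_BBAA = unname(cnt["BBAA"]), n_ABBA = unname(cnt["ABBA"]),
                 n_BABA = unname(cnt["BABA"]),
                 n_total_informative = as.integer(n_loci),
                 taxon_order = c(m1$label, m2$label),
                 n_skipped_missing = 0L,
                 n_skipped_polymorphic_outgroup = 0L,
                 n_noninformative = 0L),
            class = "site_pattern_counts")
}

#' Draw an ABC reference table from the prior
#'
#' Samples `n_sims` parameter triples (alpha, t1, t2) from independent
#' uniform priors and simulates one two-topology count vector per draw (the
#' simulation is vectorized; the deterministic `round` split is used).
#'
#' @param n_sims Number of prior-predictive simulations.
#' @param n_loci Loci per simulated dataset.
#' @param master_seed Integer seed making the whole table reproducible.
#' @param prior List of ranges: `alpha` (default c(0, 1)), `t1`, `t2`
#'   (default c(0, 5) coalescent units).
#' @param concordant Character(2): concordant class of topology X1 and X2
#'   (default BBAA and BABA, the hybrid-with-steppe vs hybrid-with-aurochs
#'   arrangements for the (HYBRID, SOURCE_B, SOURCE_C, OUTGROUP) quartet).
#' @return A `parameter_draws` object: `params` data.frame (alpha, t1, t2),
#'   `counts` matrix (n_sims x 3, columns BBAA/ABBA/BABA), the prior spec,
#'   `n_loci`, `master_seed`, `concordant`.
#' @export
draw_prior <- function(n_sims, n_loci, master_seed,
                       prior = list(alpha = c(0, 1), t1 = c(0, 5),
                                    t2 = c(0, 5)),
                       concordant = c("BBAA", "BABA")) {
  if (!is_count(n_sims) || n_sims < 1) stopf("n_sims must be >= 1")
  for (p in c("alpha", "t1", "t2")) {
    r <- prior[[p]]
    if (is.null(r) || length(r) != 2L || r[2L] < r[1L])
      stopf("prior range for %s must be c(lo, hi) with hi >= lo", p)
  }
  if (any(prior$alpha < 0) || any(prior$alpha > 1))
    stopf("alpha prior must lie within [0, 1]")
  if (prior$t1[1L] < 0 || prior$t2[1L] < 0) stopf("t priors must be >= 0")
  concordant <- match.arg(concordant, PATTERN_CLASSES, several.ok = TRUE)
  stopifnot(length(concordant) == 2L)

  with_seed(master_seed, {
    alpha <- stats::runif(n_sims, prior$alpha[1L], prior$alpha[2L])
    t1 <- stats::runif(n_sims, prior$t1[1L], prior$t1[2L])
    t2 <- stats::runif(n_sims, prior$t2[1L], prior$t2[2L])
    P1 <- pattern_probs_t(t1, concordant[1L])
    P2 <- pattern_probs_t(t2, concordant[2L])
    n1 <- as.integer(round(alpha * n_loci))
    counts <- rmultinom_rows(n1, P1) + rmultinom_rows(as.integer(n_loci) - n1, P2)
    colnames(counts) <- PATTERN_CLASSES
    stopifnot(all(rowSums(counts) == n_loci))
    structure(list(params = data.frame(alpha = alpha, t1 = t1, t2 = t2),
                   counts = counts, prior = prior,
                   n_sims = as.integer(n_sims), n_loci = as.integer(n_loci),
                   master_seed = as.integer(master_seed),
                   concordant = concordant),
              class = "parameter_draws")
  })
}

#' @export
print.parameter_draws <- function(x, ...) {
  cat(sprintf("parameter_draws: %d simulations x %d loci (seed %d)\n",
              x$n_sims, x$n_loci, x$master_seed))
  cat(sprintf("  topologies concordant for %s (X1) and %s (X2)\n",
              x$concordant[1L], x$concordant[2L]))
  invisible(x)
}

#' Serialize a reference table as TSV plus a JSON sidecar
#'
#' TSV columns: alpha, t1, t2, n_BBAA, n_ABBA, n_BABA. The sidecar holds the
#' prior specification, locus count and master seed.
#'
#' @param draws A `parameter_draws`.
#' @param path Output TSV path (sidecar written as `<path>.json`).
#' @export
write_reference_table <- function(draws, path) {
  stopifnot(inherits(draws, "parameter_draws"))
  tab <- cbind(draws$params,
               stats::setNames(as.data.frame(draws$counts),
                               paste0("n_", PATTERN_CLASSES)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(prior = draws$prior, n_sims = draws$n_sims,
                            n_loci = draws$n_loci,
                            master_seed = draws$master_seed,
                            concordant = draws$concordant),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
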