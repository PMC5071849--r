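# Genotype-level generator with the statistical structure the analysis
# assumes: an admixture graph (outgroup; aurochs; bison clade with sister
# taxon and steppe bison; hybrid = alpha * steppe + (1 - alpha) * aurochs),
# Balding-Nichols per-branch drift, pseudo-haploid sampling and
# ancient-DNA-scale missingness.

SIM_BRANCHES <- c("OUTGROUP", "BOVID", "SOURCE_C", "BISON", "SISTER_A",
                  "SOURCE_B", "HYBRID", "HYBRID2")
SIM_ROLES <- c("HYBRID", "HYBRID2", "SOURCE_B", "SOURCE_C", "SISTER_A",
               "OUTGROUP")

# drift per branch scales with divergence: the outgroup (sheep) split and
# the aurochs/bison genus split are deep, so many panel loci are near-fixed
# differences between the two source taxa; within-bison branches are
# shallower; the hybrid founding branch carries a severe bottleneck (few
# founders), the post-divergence hybrid-lineage branches are short
default_drift <- c(OUTGROUP = 0.80, BOVID = 0.30, SOURCE_C = 0.50,
                   BISON = 0.30, SOURCE_B = 0.20, SISTER_A = 0.10,
                   HYBRID = 0.20, HYBRID2 = 0.05)
# ancient roles (hybrid lineages, steppe bison) are heavily missing; modern
# comparators (cattle, American bison, sheep) nearly complete
default_missing <- c(HYBRID = 0.5, HYBRID2 = 0.5, SOURCE_B = 0.5,
                     SOURCE_C = 0.05, SISTER_A = 0.05, OUTGROUP = 0.02)
# sample counts mirror the study regime: several ancient individuals per
# hybrid lineage, exactly two steppe bison, modern reference panels for
# cattle, American bison and sheep
default_n_samples <- c(HYBRID = 4L, HYBRID2 = 4L, SOURCE_B = 2L,
                       SOURCE_C = 4L, SISTER_A = 4L, OUTGROUP = 2L)

#' Parameters for the admixture-graph genotype simulator
#'
#' @param n_loci Number of unlinked biallelic loci (default 10000, the scale
#'   of the SNP-capture panel the analysis targets).
#' @param alpha Steppe-bison (`SOURCE_B`) fraction of the hybrid lineage's
#'   ancestry, in [0, 1] (default 0.9).
#' @param drift Named vector of Balding-Nichols F values in [0, 1) per
#'   branch (`OUTGROUP`, `BOVID`, `SOURCE_C`, `BISON`, `SISTER_A`,
#'   `SOURCE_B`, `HYBRID`, `HYBRID2`); partial vectors override defaults.
#' @param root_freq_beta Shape pair (a, b) of the Beta ancestral-frequency
#'   distribution (default c(2, 2), emulating the common-variant bias of an
#'   ascertained SNP panel).
#' @param missing_rate Named per-role missing-call fractions in [0, 1);
#'   partial vectors override defaults (ancient roles 0.5, modern 0.02-0.05).
#' @param n_samples Named per-role sample counts; partial overrides.
#' @param n_hybrid_lineages 1 (default) or 2 (adds a `HYBRID2` lineage for
#'   the sharing test).
#' @param hybrid_origin For two lineages: `"single"` (both descend from one
#'   hybrid ancestor) or `"independent"` (two independent alpha-mixtures).
#' @param ploidy Output representation: `"pseudo-haploid"` (default, one
#'   sampled allele per call) or `"diploid"`.
#' @param seed Integer seed; identical parameters give identical output.
#' @return A validated `graph_sim_params` list.
#' @export
graph_sim_params <- function(n_loci = 10000L, alpha = 0.9,
                             drift = character(0),
                             root_freq_beta = c(2, 2),
                             missing_rate = character(0),
                             n_samples = character(0),
                             n_hybrid_lineages = 1L,
                             hybrid_origin = c("single", "independent"),
                             ploidy = c("pseudo-haploid", "diploid"),
                             seed = 1L) {
  hybrid_origin <- match.arg(hybrid_origin)
  ploidy <- match.arg(ploidy)
  if (!is_count(n_loci) || n_loci < 1) stopf("n_loci must be a positive integer")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  merge_named <- function(def, ov, lo, hi, what) {
    if (length(ov)) {
      bad <- setdiff(names(ov), names(def))
      if (length(bad)) stopf("unknown %s name(s): %s", what,
                             paste(bad, collapse = ", "))
      def[names(ov)] <- ov
    }
    if (any(def < lo | def >= hi)) stopf("%s values must lie in [%g, %g)", what, lo, hi)
    def
  }
  drift <- merge_named(default_drift, drift, 0, 1, "drift")
  missing_rate <- merge_named(default_missing, missing_rate, 0, 1, "missing_rate")
  ns <- default_n_samples
  if (length(n_samples)) {
    bad <- setdiff(names(n_samples), names(ns))
    if (length(bad)) stopf("unknown n_samples name(s): %s", paste(bad, collapse = ", "))
    ns[names(n_samples)] <- as.integer(n_samples)
  }
  if (any(ns < 1L)) stopf("n_samples must be >= 1 per role")
  if (length(root_freq_beta) != 2L || any(root_freq_beta <= 0))
    stopf("root_freq_beta must be two positive shapes")
  if (!n_hybrid_lineages %in% c(1L, 2L)) stopf("n_hybrid_lineages must be 1 or 2")
  structure(list(n_loci = as.integer(n_loci), alpha = alpha, drift = drift,
                 root_freq_beta = root_freq_beta, missing_rate = missing_rate,
                 n_samples = ns, n_hybrid_lineages = as.integer(n_hybrid_lineages),
                 hybrid_origin = hybrid_origin, ploidy = ploidy,
                 seed = as.integer(seed)),
            class = "graph_sim_params")
}

# Balding-Nichols drift: p_child ~ Beta(p(1-F)/F, (1-p)(1-F)/F); preserves the
# mean E[p_child] = p and is exact (no drift) at F = 0
bn_drift <- function(p, F) {
  if (F == 0) return(p)
  s <- (1 - F) / F
  out <- p
  mid <- p > 0 & p < 1
  out[mid] <- stats::rbeta(sum(mid), p[mid] * s, (1 - p[mid]) * s)
  out
}

#' Simulate genotypes under the admixture graph
#'
#' Per locus: an ancestral frequency is drawn from Beta(a, b); each branch
#' applies Balding-Nichols drift; the hybrid lineage's frequency is
#' alpha * p_steppe + (1 - alpha) * p_aurochs followed by hybrid-branch
#' drift. Genotypes are sampled binomially per sample (one allele for
#' pseudo-haploid output, two for diploid), then masked at the per-role
#' missing rate.
#'
#' @param params A `graph_sim_params`.
#' @return List with `genotypes` (a `genotype_matrix`), `pop_map` (a
#'   `population_map` wiring roles to the simulated populations) and `truth`
#'   (a `truth_record` holding the parameters and latent per-population
#'   frequencies).
#' @export
simulate_graph_genotypes <- function(params) {
  stopifnot(inherits(params, "graph_sim_params"))
  L <- params$n_loci
  with_seed(params$seed, {
    p0 <- stats::rbeta(L, params$root_freq_beta[1L], params$root_freq_beta[2L])
    p_out <- bn_drift(p0, params$drift[["OUTGROUP"]])
    p_bovid <- bn_drift(p0, params$drift[["BOVID"]])
    p_aur <- bn_drift(p_bovid, params$drift[["SOURCE_C"]])
    p_bison <- bn_drift(p_bovid, params$drift[["BISON"]])
    p_sis <- bn_drift(p_bison, params$drift[["SISTER_A"]])
    p_stp <- bn_drift(p_bison, params$drift[["SOURCE_B"]])

    mix <- params$alpha * p_stp + (1 - params$alpha) * p_aur
    if (params$n_hybrid_lineages == 1L) {
      p_hyb <- list(HYBRID = bn_drift(mix, params$drift[["HYBRID"]]))
    } else if (params$hybrid_origin == "single") {
      shared <- bn_drift(mix, params$drift[["HYBRID"]])
      p_hyb <- list(HYBRID = bn_drift(shared, params$drift[["HYBRID2"]]),
                    HYBRID2 = bn_drift(shared, params$drift[["HYBRID2"]]))
    } else {
      # independent hybridization events: same source mixture, but each
      # lineage experiences its own founding drift (no shared hybrid branch)
      p_hyb <- list(HYBRID = bn_drift(bn_drift(mix, params$drift[["HYBRID"]]),
                                      params$drift[["HYBRID2"]]),
                    HYBRID2 = bn_drift(bn_drift(mix, params$drift[["HYBRID"]]),
                                       params$drift[["HYBRID2"]]))
    }

    pop_freq <- cbind(OUTGROUP = p_out, SOURCE_C = p_aur, SISTER_A = p_sis,
                      SOURCE_B = p_stp,
                      do.call(cbind, p_hyb))
    roles <- colnames(pop_freq)

    per_call <- if (params$ploidy == "diploid") 2L else 1L
    cols <- list(); samples <- character(0); assign <- character(0)
    for (r in roles) {
      k <- params$n_samples[[r]]
      g <- matrix(stats::rbinom(L * k, per_call, pop_freq[, r]), L, k)
      if (per_call == 1L) g <- g * 2L
      mr <- params$missing_rate[[r]]
      if (mr > 0) g[matrix(stats::runif(L * k) < mr, L, k)] <- NA_integer_
      s <- sprintf("%s_%d", tolower(r), seq_len(k))
      cols[[r]] <- g
      samples <- c(samples, s)
      assign <- c(assign, stats::setNames(rep(tolower(r), k), s))
    }
    calls <- do.call(cbind, cols)

    loci <- data.frame(chrom = "1", pos = seq_len(L),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    gm <- genotype_matrix(loci, samples, calls, ploidy = params$ploidy)
    role_map <- stats::setNames(tolower(roles), roles)
    pm <- population_map(assign, roles = role_map)
    truth <- structure(list(params = params, pop_freq = pop_freq),
                       class = "truth_record")
    list(genotypes = gm, pop_map = pm, truth = truth)
  })
}

#' Fixture-suite manifest
#'
#' The documented set of datasets written by [make_fixture_suite()].
#' @return Character vector of fixture base names.
#' @export
fixture_manifest <- function() {
  c("null_no_admixture", "alpha_0.1", "alpha_0.5", "alpha_0.9",
    "single_origin", "independent_origin", "all_missing")
}

#' Write a deterministic suite of small test datasets
#'
#' For each fixture in [fixture_manifest()], writes `<name>.vcf`,
#' `<name>.pops.tsv` and `<name>.truth.json` into `out_dir`: a no-admixture
#' null (alpha = 1), alpha in \{0.1, 0.5, 0.9\}, single-origin vs independent
#' double-hybridization variants, and an all-missing pathological case.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Master seed; the same seed yields byte-identical files.
#' @param n_loci Loci per fixture (default 1000).
#' @return Invisibly, the paths of the files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, n_loci = 1000L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- list(
    null_no_admixture = list(alpha = 1),
    `alpha_0.1` = list(alpha = 0.1),
    `alpha_0.5` = list(alpha = 0.5),
    `alpha_0.9` = list(alpha = 0.9),
    single_origin = list(alpha = 0.9, n_hybrid_lineages = 2L,
                         hybrid_origin = "single"),
    independent_origin = list(alpha = 0.9, n_hybrid_lineages = 2L,
                              hybrid_origin = "independent"),
    all_missing = list(alpha = 0.9,
                       missing_rate = c(HYBRID = 0.999)))
  files <- character(0)
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    args <- c(specs[[i]], list(n_loci = n_loci, seed = seed + i))
    params <- do.call(graph_sim_params, args)
    sim <- simulate_graph_genotypes(params)
    vcf <- file.path(out_dir, paste0(nm, ".vcf"))
    tsv <- file.path(out_dir, paste0(nm, ".pops.tsv"))
    js <- file.path(out_dir, paste0(nm, ".truth.json"))
    write_vcf(sim$genotypes, vcf)
    write_population_map(sim$pop_map, tsv)
    p <- sim$truth$params
    jsonlite::write_json(list(fixture = nm, n_loci = p$n_loci,
                              alpha = p$alpha, drift = as.list(p$drift),
                              missing_rate = as.list(p$missing_rate),
                              n_hybrid_lineages = p$n_hybrid_lineages,
                              hybrid_origin = p$hybrid_origin,
                              roles = as.list(sim$pop_map$roles),
                              seed = p$seed),
                         js, auto_unbox = TRUE, digits = NA)
    files <- c(files, vcf, tsv, js)
  }
  jsonlite::write_json(fixture_manifest(),
                       file.path(out_dir, "manifest.json"), digits = NA)
  invisible(c(files, file.path(out_dir, "manifest.json")))
}
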