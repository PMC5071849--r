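# Orchestration: load -> haploidize -> D topology ranking -> f4 ratios ->
# site patterns + ABC -> sharing test, from one validated configuration.

PIPELINE_KEYS <- c("vcf", "pop_tsv", "roles", "block_size", "abc",
                   "thresholds", "seed", "out_dir")
ABC_KEYS <- c("n_sims", "tolerance", "n_posterior", "priors", "seed")

#' Build and validate a pipeline configuration
#'
#' @param vcf Path to the biallelic SNP VCF.
#' @param pop_tsv Path to the two-column sample/population TSV.
#' @param roles Named character vector mapping roles (HYBRID, SOURCE_B,
#'   SOURCE_C, SISTER_A, OUTGROUP, optionally HYBRID2) to populations.
#' @param block_size Jackknife block size in loci (default 200).
#' @param abc List: `n_sims` (default 10000), `n_posterior` (default 500,
#'   overrides `tolerance` as n_posterior/n_sims) or `tolerance`, `priors`
#'   (passed to [draw_prior()]), `seed`.
#' @param thresholds Minority-ancestry thresholds for posterior probabilities
#'   (default c(0.01, 0.05)).
#' @param seed Master seed for haploidization and representative draws.
#' @param out_dir Output directory for reports and intermediates.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(vcf, pop_tsv, roles, block_size = 200L,
                            abc = list(), thresholds = c(0.01, 0.05),
                            seed = 1L, out_dir = tempfile("bisonmix_run_")) {
  cfg <- list(vcf = vcf, pop_tsv = pop_tsv, roles = roles,
              block_size = block_size, abc = abc, thresholds = thresholds,
              seed = seed, out_dir = out_dir)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stopf("pipeline config: unknown key(s): %s", paste(unknown, collapse = ", "))
  for (k in c("vcf", "pop_tsv", "roles")) {
    if (is.null(cfg[[k]])) stopf("pipeline config: missing required key '%s'", k)
  }
  roles <- unlist(cfg$roles)
  need <- c("HYBRID", "SOURCE_B", "SOURCE_C", "SISTER_A", "OUTGROUP")
  miss <- setdiff(need, names(roles))
  if (length(miss))
    stopf("pipeline config: role(s) not mapped: %s", paste(miss, collapse = ", "))
  cfg$roles <- roles
  abc <- cfg$abc %||% list()
  unknown <- setdiff(names(abc), ABC_KEYS)
  if (length(unknown))
    stopf("pipeline config: unknown abc key(s): %s", paste(unknown, collapse = ", "))
  abc$n_sims <- abc$n_sims %||% 10000L
  if (!is.null(abc$n_posterior)) {
    abc$tolerance <- abc$n_posterior / abc$n_sims
  } else {
    abc$tolerance <- abc$tolerance %||% (500 / abc$n_sims)
  }
  abc$seed <- abc$seed %||% (cfg$seed %||% 1L)
  cfg$abc <- abc
  cfg$block_size <- cfg$block_size %||% 200L
  cfg$thresholds <- cfg$thresholds %||% c(0.01, 0.05)
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the keys of [pipeline_config()]; relative input
#'   paths are resolved against the YAML's directory.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("vcf", "pop_tsv")) {
    if (!is.null(y[[k]]) && !file.exists(y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  }
  validate_pipeline_config(y)
}

run_stage <- function(name, expr) {
  log_msg("[%s] ...", name)
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full admixture-inference pipeline
#'
#' Stages: load VCF and population map; pseudo-haploidize if diploid; rank
#' the three ingroup topologies by D; estimate steppe/aurochs ancestry by f4
#' ratio for each hybrid lineage; count site patterns and run
#' rejection + ridge ABC against a two-topology reference table simulated at
#' the observed number of informative loci; report posterior probabilities of
#' minimum aurochs ancestry at the configured thresholds; if a second hybrid
#' lineage is mapped, run the derived-allele sharing test. All outputs are
#' written under `cfg$out_dir`.
#'
#' @param cfg A `pipeline_config` (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @return A `report_bundle` with the stage results and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  pops <- run_stage("load", {
    read_population_map(cfg$pop_tsv, roles = cfg$roles)
  })
  g <- run_stage("load", read_vcf(cfg$vcf, pops))
  g <- run_stage("haploidize", {
    if (g$ploidy == "diploid") haploidize(g, seed = cfg$seed) else g
  })

  ranking <- run_stage("dstat", {
    rank_topologies(g, pops, block_size = cfg$block_size)
  })
  write_dstat_report(ranking, file.path(cfg$out_dir, "topology_ranking.tsv"))

  hybrid_roles <- intersect(c("HYBRID", "HYBRID2"), names(pops$roles))
  estimates <- run_stage("f4ratio", {
    stats::setNames(lapply(hybrid_roles, function(r)
      f4_ratio(g, pops, block_size = cfg$block_size, hybrid_role = r)),
      hybrid_roles)
  })
  ancestry <- ancestry_report(estimates)
  utils::write.table(ancestry, file.path(cfg$out_dir, "ancestry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  observed <- run_stage("site_patterns", {
    site_pattern_counts(g, pops,
                        quartet = c("HYBRID", "SOURCE_B", "SOURCE_C",
                                    "OUTGROUP"),
                        seed = cfg$seed)
  })
  abc_res <- run_stage("abc", {
    ref <- draw_prior(n_sims = cfg$abc$n_sims,
                      n_loci = observed$n_total_informative,
                      master_seed = cfg$abc$seed,
                      prior = cfg$abc$priors %||%
                        list(alpha = c(0, 1), t1 = c(0, 5), t2 = c(0, 5)))
    post <- ridge_adjust(abc_reject(observed, ref, cfg$abc$tolerance))
    probs <- vapply(cfg$thresholds, function(th)
      posterior_probability(post, th), numeric(1L))
    list(posterior = post,
         threshold_probs = stats::setNames(probs,
                                           sprintf("aurochs_ge_%g", cfg$thresholds)))
  })
  write_posterior(abc_res$posterior, file.path(cfg$out_dir, "posterior.tsv"))

  sharing <- NULL
  if ("HYBRID2" %in% names(pops$roles)) {
    sharing <- run_stage("sharing", {
      sharing_test(classify_loci(g, pops, seed = cfg$seed))
    })
    write_sharing_result(sharing, file.path(cfg$out_dir, "sharing.json"),
                         file.path(cfg$out_dir, "sharing_loci.tsv"))
  }

  report <- structure(list(config = cfg,
                           topology = ranking,
                           ancestry = ancestry,
                           estimates = estimates,
                           observed_patterns = observed,
                           abc = abc_res,
                           sharing = sharing,
                           provenance = list(
                             seed = cfg$seed, abc_seed = cfg$abc$seed,
                             n_loci = n_loci(g),
                             vcf = normalizePath(cfg$vcf))),
                      class = "report_bundle")
  write_report_json(report, file.path(cfg$out_dir, "report.json"))
  report
}

write_report_json <- function(report, path) {
  est <- report$estimates
  jsonlite::write_json(list(
    topology = report$topology$results,
    best_topology = report$topology$results$arrangement[report$topology$best],
    ancestry = report$ancestry,
    abc = list(
      n_accepted = report$abc$posterior$n_accepted,
      tolerance = report$abc$posterior$tolerance,
      posterior_mean_alpha = mean(report$abc$posterior$adjusted$alpha),
      threshold_probs = as.list(report$abc$threshold_probs)),
    sharing = if (!is.null(report$sharing)) list(
      N = report$sharing$table$N, K = report$sharing$table$K,
      n = report$sharing$table$n, k = report$sharing$table$k,
      expected_k = report$sharing$expected_k,
      p_upper = report$sharing$p_upper),
    provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== bisonmix pipeline report ==\n\nTopology ranking (D-statistics):\n")
  print(x$topology)
  cat("\nAncestry proportions (f4 ratio):\n")
  print(x$ancestry, row.names = FALSE)
  cat("\nABC posterior:\n")
  print(x$abc$posterior)
  for (nm in names(x$abc$threshold_probs))
    cat(sprintf("  P(%s) = %.1f%%\n", nm, x$abc$threshold_probs[[nm]]))
  if (!is.null(x$sharing)) { cat("\n"); print(x$sharing) }
  invisible(x)
}
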