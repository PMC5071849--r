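# five roles, two samples per source, one per hybrid lineage + outgroup;
# with fixed duplicate source samples every lineage state is deterministic
sharing_gm <- function(states) {
  # states: n x 5 over {"A","B",NA}, columns (aurochs, steppe, h1, h2, out)
  full <- cbind(aur1 = states[, 1], aur2 = states[, 1],
                stp1 = states[, 2], stp2 = states[, 2],
                hy1 = states[, 3], hy2 = states[, 4], out = states[, 5])
  g <- gm_from_states(full)
  pm <- population_map(
    c(aur1 = "aur", aur2 = "aur", stp1 = "stp", stp2 = "stp",
      hy1 = "w", hy2 = "cx", out = "sheep"),
    roles = c(SOURCE_C = "aur", SOURCE_B = "stp", HYBRID = "w",
              HYBRID2 = "cx", OUTGROUP = "sheep"))
  list(g = g, pm = pm)
}

test_that("classify_loci tallies the diagnostic-locus contingency exactly", {
  states <- rbind(
    c("A", "B", "B", "B", "A"),   # informative; both hybrids derived
    c("B", "B", "B", "B", "A"),   # aurochs derived: excluded
    c("A", "A", "B", "B", "A"),   # steppe not derived: excluded
    c("A", "B", "A", "B", "A"),   # informative; only hybrid2 derived
    c("A", "B", "B", "A", "A"),   # informative; only hybrid1 derived
    c("A", "B", NA, "B", "A"),    # hybrid1 missing: excluded
    c("B", "A", "A", "A", "B"))   # polarity flips: informative, both derived
  fx <- sharing_gm(states)
  tb <- classify_loci(fx$g, fx$pm, seed = 1)
  expect_equal(tb$N, 4L)
  expect_equal(tb$K, 3L)
  expect_equal(tb$n, 3L)
  expect_equal(tb$k, 2L)
})

test_that("classify_loci matches per-locus enumeration and ignores locus order", {
  set.seed(41)
  states <- matrix(sample(c("A", "B", NA), 1000 * 5, TRUE, c(0.5, 0.4, 0.1)),
                   1000, 5)
  fx <- sharing_gm(states)
  tb <- classify_loci(fx$g, fx$pm, seed = 3)

  # naive loop
  N <- K <- n <- k <- 0L
  for (i in seq_len(1000)) {
    s <- states[i, ]
    if (anyNA(s)) next
    if (s[1] != s[5] || s[2] == s[5]) next
    N <- N + 1L
    d1 <- s[3] != s[5]; d2 <- s[4] != s[5]
    K <- K + d1; n <- n + d2; k <- k + (d1 && d2)
  }
  expect_equal(tb$N, N)
  expect_equal(tb$K, K)
  expect_equal(tb$n, n)
  expect_equal(tb$k, k)
  expect_true(tb$k <= min(tb$K, tb$n) && tb$K <= tb$N && tb$n <= tb$N)

  # shuffled loci give the same table
  perm <- sample.int(1000)
  fx2 <- sharing_gm(states[perm, ])
  tb2 <- classify_loci(fx2$g, fx2$pm, seed = 3)
  expect_equal(tb2[c("N", "K", "n", "k")], tb[c("N", "K", "n", "k")])
})

test_that("hypergeometric upper tail is exact, normalized, and symmetric in the two lineages", {
  expect_equal(hypergeom_upper_tail(100, 40, 30, 0), 1)
  expect_equal(hypergeom_upper_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)

  # large-count case against direct log-space summation
  expect_equal(hypergeom_upper_tail(10000, 2000, 1000, 300),
               oracle_hyper_upper(10000, 2000, 1000, 300),
               tolerance = 1e-10)

  # the pmf sums to one over its support
  expect_equal(sum(oracle_hyper_pmf(500, 130, 77)), 1, tolerance = 1e-12)

  # swapping K and n leaves the tail unchanged
  expect_equal(hypergeom_upper_tail(5000, 900, 400, 120),
               hypergeom_upper_tail(5000, 400, 900, 120), tolerance = 1e-12)

  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "k > min")
  expect_error(hypergeom_upper_tail(10, 11, 4, 2), "exceed N")
})

test_that("sharing_test sits near p = 0.5 at the expected overlap and flags nothing", {
  tb <- structure(list(N = 1000L, K = 500L, n = 400L, k = 200L,
                       hybrid_roles = c("HYBRID", "HYBRID2"),
                       min_obs = 2L, loci = NULL, n_excluded = 0L),
                  class = "derived_allele_table")
  res <- sharing_test(tb)
  expect_equal(res$expected_k, 200)
  expect_gt(res$p_upper, 0.3)
  expect_lt(res$p_upper, 0.7)
  expect_false(res$excess_sharing)
})

test_that("single-origin hybrids show excess derived-allele sharing", {
  pv <- vapply(1:100, function(i) {
    s <- simulate_graph_genotypes(graph_sim_params(
      alpha = 0.9, n_hybrid_lineages = 2L, hybrid_origin = "single",
      seed = 150000 + i))
    sharing_test(classify_loci(s$genotypes, s$pop_map, seed = i))$p_upper
  }, 1)
  expect_gte(mean(pv < 0.05), 0.90)
})
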