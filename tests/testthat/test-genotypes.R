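test_that("read_vcf keeps only biallelic SNPs and maps GT codes", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(p, c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT\t0/0\t1/1",   # tri-allelic: dropped
    "1\t300\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t1/1"))
  g <- suppressMessages(read_vcf(p))
  expect_equal(n_loci(g), 2L)
  expect_equal(g$loci$pos, c(100L, 300L))
  expect_equal(unname(g$calls[1, ]), c(0L, 1L))
  expect_true(is.na(g$calls[2, "s1"]))        # ./. maps to MISSING
  expect_equal(unname(g$calls[2, "s2"]), 2L)
  expect_identical(g$ploidy, "diploid")
})

test_that("read_vcf fails on mapped samples missing from the header and on empty panels", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(p, "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1")
  pm <- population_map(c(s1 = "pop1", ghost = "pop2"))
  expect_error(suppressMessages(read_vcf(p, pm)), "ghost")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(p2, "1\t100\t.\tA\tGT\t.\tPASS\t.\tGT\t0/0\t0/1")  # indel only
  expect_error(suppressMessages(read_vcf(p2)), "biallelic")
})

test_that("write_vcf / read_vcf round-trips the generator's matrices", {
  sim <- simulate_graph_genotypes(graph_sim_params(n_loci = 1000L, seed = 5L))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, p)
  g2 <- suppressMessages(read_vcf(p, sim$pop_map))
  expect_identical(g2$ploidy, "pseudo-haploid")
  expect_equal(g2$loci, sim$genotypes$loci)
  expect_identical(g2$samples, sim$genotypes$samples)
  expect_identical(unname(g2$calls), unname(sim$genotypes$calls))

  # diploid round trip as well
  simd <- simulate_graph_genotypes(graph_sim_params(n_loci = 500L,
                                                    ploidy = "diploid",
                                                    seed = 6L))
  write_vcf(simd$genotypes, p)
  g3 <- suppressMessages(read_vcf(p))
  expect_identical(g3$ploidy, "diploid")
  expect_identical(unname(g3$calls), unname(simd$genotypes$calls))
})

test_that("haploidize: identity without heterozygotes, deterministic, binomially fair", {
  # no heterozygotes: values unchanged
  g0 <- gm_from_states(matrix(c("A", "B", NA, "B"), 2), c("a", "b"))
  gd <- genotype_matrix(g0$loci, g0$samples, g0$calls, ploidy = "diploid")
  h0 <- haploidize(gd, seed = 1)
  expect_identical(unname(h0$calls), unname(gd$calls))
  expect_identical(h0$ploidy, "pseudo-haploid")

  # determinism and warning no-op on pseudo-haploid input
  loci <- data.frame(chrom = "1", pos = 1:5000, ref = "A", alt = "G")
  calls <- matrix(1L, 5000, 2)
  gh <- genotype_matrix(loci, c("x", "y"), calls, ploidy = "diploid")
  h1 <- haploidize(gh, seed = 42)
  h2 <- haploidize(gh, seed = 42)
  expect_identical(h1$calls, h2$calls)
  expect_warning(h3 <- haploidize(h1, seed = 1), "already")
  expect_identical(h3$calls, h1$calls)

  # 10,000 het calls: fraction resolved to alt within the central 99%
  # binomial(10000, 1/2) interval
  n2 <- sum(h1$calls == 2L)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(n2, bounds[1])
  expect_lte(n2, bounds[2])
})

test_that("allele_freqs matches naive per-cell tallies", {
  # single pseudo-haploid observation
  g1 <- gm_from_states(matrix("B", 1, 1), "s")
  pm1 <- population_map(c(s = "p"), roles = c(HYBRID = "p"))
  expect_equal(unname(allele_freqs(g1, pm1)$freq[1, "p"]), 1.0)

  # diploid calls {0, 1, 2} pool to 3/6
  loci <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G")
  g2 <- genotype_matrix(loci, c("a", "b", "c"),
                        matrix(c(0L, 1L, 2L), 1), ploidy = "diploid")
  pm2 <- population_map(c(a = "p", b = "p", c = "p"))
  expect_equal(unname(allele_freqs(g2, pm2)$freq[1, "p"]), 0.5)

  # random matrix vs brute force, exact
  g <- random_gm(200, paste0("s", 1:6), miss = 0.3, seed = 9)
  pm <- population_map(stats::setNames(rep(c("p1", "p2", "p3"), each = 2),
                                       paste0("s", 1:6)))
  fr <- allele_freqs(g, pm)
  for (p in c("p1", "p2", "p3")) {
    s <- names(pm$assignments)[pm$assignments == p]
    for (i in c(1, 17, 50, 200)) {
      expect_identical(unname(fr$freq[i, p]), oracle_freq(g$calls[i, s], per_call = 2))
    }
  }
})

test_that("site_pattern_counts classifies the canonical quartet patterns", {
  states <- rbind(c("B", "B", "A", "A"),
                  c("A", "B", "B", "A"),
                  c("B", "A", "B", "A"),
                  c("A", "A", "A", "A"))
  colnames(states) <- c("s_p1", "s_p2", "s_p3", "s_o")
  g <- gm_from_states(states)
  pm <- pm_single(c("P1", "P2", "P3", "O"))
  sp <- site_pattern_counts(g, pm, quartet = c("P1", "P2", "P3", "O"),
                            seed = 1)
  expect_equal(sp$n_BBAA, 1L)
  expect_equal(sp$n_ABBA, 1L)
  expect_equal(sp$n_BABA, 1L)
  expect_equal(sp$n_total_informative, 3L)
  expect_equal(sp$n_noninformative, 1L)
})

test_that("site_pattern_counts errors when a role has no data", {
  states <- rbind(c("B", "B", NA, "A"), c("A", "B", NA, "A"))
  colnames(states) <- c("s_p1", "s_p2", "s_p3", "s_o")
  g <- gm_from_states(states)
  pm <- pm_single(c("P1", "P2", "P3", "O"))
  expect_error(site_pattern_counts(g, pm, c("P1", "P2", "P3", "O")),
               "zero informative")
})

test_that("site_pattern_counts agrees with per-locus enumeration on random data", {
  set.seed(31)
  states <- matrix(sample(c("A", "B", NA), 500 * 4, TRUE, c(0.45, 0.45, 0.1)),
                   500, 4,
                   dimnames = list(NULL, c("s_p1", "s_p2", "s_p3", "s_o")))
  g <- gm_from_states(states)
  pm <- pm_single(c("P1", "P2", "P3", "O"))
  sp <- site_pattern_counts(g, pm, c("P1", "P2", "P3", "O"), seed = 77)
  exp <- oracle_patterns(states)
  expect_equal(sp$n_BBAA, unname(exp["BBAA"]))
  expect_equal(sp$n_ABBA, unname(exp["ABBA"]))
  expect_equal(sp$n_BABA, unname(exp["BABA"]))
  expect_equal(sp$n_total_informative, unname(exp["informative"]))
})

test_that("site_pattern_counts is invariant to sample order and equivariant to P1/P2 relabeling", {
  sim <- simulate_graph_genotypes(graph_sim_params(n_loci = 2000L, seed = 8L))
  g <- sim$genotypes; pm <- sim$pop_map
  q <- c("HYBRID", "SOURCE_B", "SOURCE_C", "OUTGROUP")
  sp <- site_pattern_counts(g, pm, q, seed = 5)

  # permute sample columns: counts unchanged
  perm <- sample(seq_along(g$samples))
  g2 <- genotype_matrix(g$loci, g$samples[perm], g$calls[, perm],
                        ploidy = g$ploidy)
  sp2 <- site_pattern_counts(g2, pm, q, seed = 5)
  expect_equal(sp2[c("n_BBAA", "n_ABBA", "n_BABA")],
               sp[c("n_BBAA", "n_ABBA", "n_BABA")])

  # swapping P1 and P2 swaps ABBA and BABA, fixes BBAA (same seed)
  sp3 <- site_pattern_counts(g, pm, q[c(2, 1, 3, 4)], seed = 5)
  expect_equal(sp3$n_BBAA, sp$n_BBAA)
  expect_equal(sp3$n_ABBA, sp$n_BABA)
  expect_equal(sp3$n_BABA, sp$n_ABBA)
})
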