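# bisonmix

Admixture inference for hybrid-origin bison lineages from sparse ancient
SNP data.

The European bison (wisent) and its extinct Late Pleistocene relatives
carry nuclear genomes dominated by steppe bison (*Bison priscus*) ancestry
but mitochondria related to the aurochs (*Bos primigenius*) — the signature
of a hybrid origin. `bisonmix` implements the nuclear side of that analysis
for the data regime it has to survive: ~10,000 unlinked biallelic capture
loci, pseudo-haploid genotypes, 40–70% missingness in the ancient samples,
sheep as outgroup. It is aimed at population geneticists who want each step
of such an analysis as a tested, scriptable R function.

## What it computes

* **Quartet topology tests** — outgroup-polarized site-pattern counts
  (BBAA/ABBA/BABA) and the D statistic

  `D = Σ (x−w)(y−z) / Σ (w+x−2wx)(y+z−2yz)`

  (count form `(nABBA − nBABA)/(nABBA + nBABA)`), with weighted
  delete-one-block jackknife standard errors; `rank_topologies()` evaluates
  the three sister pairings of three ingroup populations and flags
  arrangements rejected at |Z| > 3.
* **Ancestry proportions** — the f4 ratio
  `α = f4(A,O; H,C) / f4(A,O; B,C)` for the steppe fraction of a hybrid
  lineage's ancestry, jackknifed by recomputing the ratio per deleted
  block.
* **Likelihood-free cross-check** — a two-topology multinomial simulator
  (concordant pattern probability `1 − (2/3)e^(−t)`), rejection ABC on
  standardized counts with local-linear ridge adjustment, posterior
  probabilities of minimum minority ancestry, and `cv4abc()` leave-one-out
  prediction error in s.d. units.
* **Single vs multiple hybridization** — diagnostic-locus classification
  (aurochs fixed ancestral, steppe fixed derived) and an exact
  hypergeometric upper-tail test of derived-allele sharing between two
  hybrid lineages.
* **A validation generator** — an admixture-graph genotype simulator
  (Balding–Nichols drift, pseudo-haploid sampling, per-role missingness)
  with truth records, plus `make_fixture_suite()` for deterministic test
  datasets.
* **Orchestration** — `run_pipeline()` runs load → haploidize → D ranking →
  f4 ratios → ABC → sharing test from one (YAML) config and writes TSV/JSON
  reports; `inst/scripts/run_pipeline.R` is the command-line wrapper.

## Worked example

Simulate a study-like dataset with a known 90/10 steppe/aurochs hybrid and
run the three independent analyses:

```r
library(bisonmix)
sim <- simulate_graph_genotypes(graph_sim_params(alpha = 0.9, seed = 11))

rank_topologies(sim$genotypes, sim$pop_map)
#>                   arrangement          D         SE         Z n_informative
#>  ((HYBRID,SISTER_A),SOURCE_B) -0.1533665 0.01933247 -7.933108          7060
#>  ((HYBRID,SOURCE_B),SISTER_A)  0.0502619 0.02695800  1.864452          7060
#>  ((SISTER_A,SOURCE_B),HYBRID)  0.2020708 0.02217538  9.112395          7060
#>  n_blocks significant best
#>        50        TRUE
#>        50       FALSE   <=
#>        50        TRUE

f4_ratio(sim$genotypes, sim$pop_map)
#> f4-ratio ancestry for HYBRID: 90.6% SOURCE_B / 9.4% SOURCE_C (SE 4.8%)
#>   f4 num = 0.0391279, den = 0.0431677 over 7060 loci (50 blocks)

sp <- site_pattern_counts(sim$genotypes, sim$pop_map, seed = 11)
ref <- draw_prior(n_sims = 10000, n_loci = sp$n_total_informative,
                  master_seed = 11)
post <- ridge_adjust(abc_reject(sp, ref, tolerance = 0.05))
posterior_probability(post, 0.01)   # 95.4
posterior_probability(post, 0.05)   # 89.8
```

Reading the output: only the arrangement placing the hybrid lineage with
steppe bison survives the D test (|Z| < 3; the two alternatives are
rejected at 8–9 standard errors); the f4 ratio recovers the simulated 90%
steppe fraction as 90.6% ± 4.8%; and the ABC posterior independently puts
95.4% probability on at least 1% aurochs ancestry (89.8% on at least 5%) —
the same three-way agreement the method is designed to detect on the real
capture data.

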