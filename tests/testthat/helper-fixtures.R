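# Small in-code fixtures shared across tests.

# genotype matrix from a haploid state matrix over {"A","B",NA}: "A" = ref
# allele (call 0), "B" = alt (call 2); one column per sample
gm_from_states <- function(states, samples = colnames(states),
                           ploidy = "pseudo-haploid") {
  calls <- matrix(NA_integer_, nrow(states), ncol(states))
  calls[states == "A"] <- 0L
  calls[states == "B"] <- 2L
  loci <- data.frame(chrom = "1", pos = seq_len(nrow(states)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(loci, samples, calls, ploidy = ploidy)
}

# one sample per role; roles named by the state-matrix columns
pm_single <- function(role_names) {
  samples <- paste0("s_", tolower(role_names))
  population_map(stats::setNames(tolower(role_names), samples),
                 roles = stats::setNames(tolower(role_names), role_names))
}

# random diploid genotype matrix with missingness
random_gm <- function(n_loci, samples, miss = 0.2, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(c(0:2, NA), n_loci * length(samples), TRUE,
                         prob = c((1 - miss) / 3, (1 - miss) / 3,
                                  (1 - miss) / 3, miss)),
                  n_loci, length(samples))
  loci <- data.frame(chrom = "1", pos = seq_len(n_loci),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(loci, samples, calls, ploidy = "diploid")
}

# random freq_table (no genotype backing) for statistic-level tests
random_freq_table <- function(n_loci, pops, na_frac = 0, seed = 1) {
  set.seed(seed)
  f <- matrix(stats::runif(n_loci * length(pops)), n_loci,
              dimnames = list(NULL, pops))
  if (na_frac > 0) f[stats::runif(length(f)) < na_frac] <- NA
  structure(list(freq = f,
                 n_obs = matrix(2L * !is.na(f), n_loci,
                                dimnames = list(NULL, pops)),
                 loci = data.frame(chrom = "1", pos = seq_len(n_loci),
                                   ref = "A", alt = "G"),
                 populations = pops),
            class = "freq_table")
}

pattern_vector_of <- function(sp) c(sp$n_BBAA, sp$n_ABBA, sp$n_BABA)

# VCF text fixture writer
write_vcf_text <- function(path, records,
                           samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
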