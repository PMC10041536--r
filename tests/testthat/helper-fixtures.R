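# Small fixtures built in code.

# A variant table built directly from a dosage matrix (and optional
# haplotypes), with evenly spaced positions on one chromosome.
toy_vt <- function(dosage, haplotypes = NULL, pos = NULL, chrom = "chr1",
                   mean_depth = NULL) {
  m <- nrow(dosage)
  sites <- data.frame(chrom = rep(chrom, length.out = m),
                      pos = as.integer(if (is.null(pos)) seq(100, by = 100, length.out = m) else pos),
                      ref = rep("A", m), alt = rep("G", m),
                      stringsAsFactors = FALSE)
  if (!is.null(mean_depth)) sites$mean_depth <- mean_depth
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  new_variant_table(sites, dosage, haplotypes = haplotypes)
}

# Random small dosage matrix with the given missing rate.
random_dosage <- function(m, n, miss = 0) {
  d <- matrix(rbinom(m * n, 2L, runif(m, 0.2, 0.8)[rep(seq_len(m), n)]),
              nrow = m)
  if (miss > 0) d[runif(m * n) < miss] <- NA
  d
}

# A fast scaled-down simulation config for tests that need a full line.
test_sim_config <- function(...) {
  sim_config(pop_size = 120L, n_generations = 6L, n_chromosomes = 1L,
             chrom_length_bp = 1e6, n_snps = 300L, n_causal = 5L,
             sample_schedule = data.frame(generation = c(1L, 6L),
                                          n_males = 15L, n_females = 15L),
             drop_samples = NULL, ...)
}
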