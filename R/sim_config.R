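#' Configuration for the breeding-line simulator
#'
#' Collects every parameter of the forward-time simulation of a closed
#' breeding line under sex-specific truncation selection on an additive
#' polygenic trait (breast muscle weight, grams). Defaults reproduce the
#' study design being emulated: roughly 750 individuals per generation over
#' 10 generations, a 35--40% female and 7--8% male retention rate, and
#' cohorts of 15 males + 15 females sampled at generations 1, 4, 7 and 10
#' with one generation-4 sample lost (119 samples in total).
#'
#' The trait scale is calibrated once at the founder generation: relative
#' effect sizes are rescaled so the founder additive genetic variance equals
#' `h2 * pheno_sd^2`, and the environmental standard deviation is fixed at
#' `sqrt(1 - h2) * pheno_sd` for all later generations, so `h2` is the
#' narrow-sense heritability in the founders only.
#'
#' @param pop_size Individuals per generation.
#' @param n_generations Number of generations simulated (founders count as
#'   generation 1).
#' @param female_retention,male_retention Fraction of each sex retained as
#'   parents by phenotypic truncation, in (0, 1).
#' @param n_chromosomes,chrom_length_bp Genome layout; SNPs are spread evenly
#'   across chromosomes at uniform random positions.
#' @param n_snps Total number of biallelic SNPs.
#' @param n_causal Number of causal loci (must not exceed `n_snps`).
#' @param effect_sizes Optional vector of `n_causal` relative effect weights
#'   (alt-allele, trait units before rescaling). Default: geometric series
#'   `effect_decay^(0:(n_causal-1))`, all trait-increasing.
#' @param effect_decay Ratio of the default geometric effect-size series;
#'   the default 1 gives equal-magnitude effects (a polygenic architecture
#'   in which every causal locus responds, matching the soft-sweep regime
#'   the simulator emulates), values below 1 concentrate the variance on a
#'   few major loci.
#' @param h2 Narrow-sense heritability in the founder generation, in `[0, 1]`.
#' @param pheno_mean,pheno_sd Founder phenotypic mean and standard deviation
#'   (grams).
#' @param recomb_rate Expected crossovers per bp per meiosis (uniform, no
#'   interference).
#' @param founder_maf_law Distribution of founder minor-allele frequencies for
#'   neutral loci: `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "fixed", value=)`. The minor allele is assigned to REF or
#'   ALT at random.
#' @param causal_freq_range Range of the founder frequency of the
#'   trait-increasing (ALT) allele at causal loci.
#' @param n_founder_haplotypes Size of the ancestral haplotype pool; each
#'   founder haplotype is a mosaic of pool haplotypes (coalescent-style
#'   block structure), giving realistic background LD. `NULL` draws founder
#'   alleles independently per locus (no background LD).
#' @param founder_block_bp Mean length (bp) of the ancestry blocks in the
#'   founder mosaic (exponential lengths); `Inf` copies whole-chromosome
#'   pool haplotypes.
#' @param sample_schedule Data frame with columns `generation`, `n_males`,
#'   `n_females` describing the sequenced cohorts.
#' @param drop_samples Data frame with columns `generation`, `n`: number of
#'   sampled individuals discarded afterwards per generation (emulates lost
#'   samples; the default drops one generation-4 sample).
#' @param seed Optional integer seed applied by [run_breeding_simulation()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(pop_size = 750L,
                       n_generations = 10L,
                       female_retention = 0.375,
                       male_retention = 0.075,
                       n_chromosomes = 3L,
                       chrom_length_bp = 5e6,
                       n_snps = 3000L,
                       n_causal = 10L,
                       effect_sizes = NULL,
                       effect_decay = 1.0,
                       h2 = 0.3,
                       pheno_mean = 80,
                       pheno_sd = 32,
                       recomb_rate = 3e-8,
                       founder_maf_law = list(dist = "uniform", min = 0.05, max = 0.5),
                       causal_freq_range = c(0.1, 0.3),
                       n_founder_haplotypes = 12L,
                       founder_block_bp = 5e4,
                       sample_schedule = default_sample_schedule(),
                       drop_samples = data.frame(generation = 4L, n = 1L),
                       seed = NULL) {
  cfg <- list(
    pop_size = as.integer(pop_size), n_generations = as.integer(n_generations),
    female_retention = female_retention, male_retention = male_retention,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
    effect_sizes = effect_sizes, effect_decay = effect_decay, h2 = h2,
    pheno_mean = pheno_mean, pheno_sd = pheno_sd, recomb_rate = recomb_rate,
    founder_maf_law = founder_maf_law, causal_freq_range = causal_freq_range,
    n_founder_haplotypes = if (is.null(n_founder_haplotypes)) NULL else as.integer(n_founder_haplotypes),
    founder_block_bp = founder_block_bp,
    sample_schedule = sample_schedule, drop_samples = drop_samples,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default cohort sampling schedule
#'
#' Generations 1, 4, 7 and 10, each with 15 males and 15 females.
#' @return Data frame with columns `generation`, `n_males`, `n_females`.
#' @export
default_sample_schedule <- function() {
  data.frame(generation = c(1L, 4L, 7L, 10L), n_males = 15L, n_females = 15L)
}

validate_sim_config <- function(cfg) {
  stopf <- function(...) stop(sprintf(...), call. = FALSE)
  if (cfg$pop_size <= 0L) stopf("config error: pop_size must be positive")
  if (cfg$n_snps <= 0L) stopf("config error: n_snps must be positive")
  if (cfg$n_generations < 1L) stopf("config error: n_generations must be >= 1")
  for (f in c("female_retention", "male_retention")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stopf("config error: %s must lie strictly in (0, 1)", f)
  }
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_snps)
    stopf("config error: n_causal must be in [0, n_snps]")
  if (!is.numeric(cfg$h2) || cfg$h2 < 0 || cfg$h2 > 1)
    stopf("config error: h2 must be in [0, 1]")
  if (cfg$chrom_length_bp <= 0 || cfg$n_chromosomes <= 0L)
    stopf("config error: chromosome layout must be positive")
  if (!is.null(cfg$effect_sizes) && length(cfg$effect_sizes) != cfg$n_causal)
    stopf("config error: effect_sizes must have length n_causal")
  if (cfg$recomb_rate < 0) stopf("config error: recomb_rate must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals/generation x %d generations\n",
              x$pop_size, x$n_generations))
  cat(sprintf("  retention: %.1f%% female, %.1f%% male\n",
              100 * x$female_retention, 100 * x$male_retention))
  cat(sprintf("  genome: %d chromosomes x %.3g bp, %d SNPs (%d causal), h2 = %.2f\n",
              x$n_chromosomes, x$chrom_length_bp, x$n_snps, x$n_causal, x$h2))
  invisible(x)
}
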