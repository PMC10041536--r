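#' Breast muscle weight from caliper/ultrasound measurements
#'
#' Applies the regression linking breast muscle volume (BMV = BB x KL x BMT,
#' cm^3) to breast muscle weight: `BMW = 0.6228 * BMV + 17.042` grams.
#'
#' @param bb Breast breadth, cm.
#' @param kl Keel length, cm.
#' @param bmt Breast muscle thickness, cm.
#' @return Breast muscle weight in grams.
#' @examples
#' bmw_from_measurements(10, 10, 2) # 141.602
#' @export
bmw_from_measurements <- function(bb, kl, bmt) {
  vals <- c(bb, kl, bmt)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("invalid measurement: bb, kl and bmt must be finite and >= 0",
         call. = FALSE)
  0.6228 * (bb * kl * bmt) + 17.042
}

.bmw_slope <- 0.6228
.bmw_intercept <- 17.042

draw_founder_maf <- function(n, law) {
  switch(law$dist,
    uniform = runif(n, law$min, law$max),
    fixed = rep(law$value, n),
    beta = rbeta(n, law$shape1, law$shape2),
    stop("config error: unknown founder_maf_law dist '", law$dist, "'",
         call. = FALSE)
  )
}

#' Simulate the founder generation
#'
#' Lays out `n_snps` biallelic SNPs uniformly along the configured
#' chromosomes, draws founder allele frequencies from `founder_maf_law`
#' (causal loci from `causal_freq_range` for the trait-increasing ALT
#' allele), and builds diploid founder haplotypes either independently per
#' locus or as mosaics over a small ancestral haplotype pool
#' (`n_founder_haplotypes`), with ancestry blocks of mean length
#' `founder_block_bp` giving realistic background linkage disequilibrium.
#' Sexes are assigned 1:1. Effect sizes are rescaled so the founder additive
#' variance equals `h2 * pheno_sd^2`; the environmental standard deviation
#' fixed here is reused for every later generation.
#'
#' @param config A [sim_config()].
#' @return A `population` object: haplotype matrix (`2N x n_snps`, 0/1),
#'   `sex`, `genetic_value`, `phenotype`, `generation`, plus the site table,
#'   causal-locus registry and trait-scale constants carried through the run.
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  N <- config$pop_size
  M <- config$n_snps
  K <- config$n_chromosomes

  # genome layout: spread SNPs evenly over chromosomes, positions uniform
  per_chrom <- rep(M %/% K, K)
  if (M %% K > 0) per_chrom[seq_len(M %% K)] <- per_chrom[seq_len(M %% K)] + 1L
  chrom <- rep(sprintf("chr%d", seq_len(K)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    sort(sample.int(config$chrom_length_bp - 1L, m))), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")

  maf <- draw_founder_maf(M, config$founder_maf_law)
  flip <- runif(M) < 0.5
  p_alt <- ifelse(flip, 1 - maf, maf)   # ALT-allele founder frequency

  causal_idx <- integer(0)
  effects <- numeric(0)
  if (config$n_causal > 0L) {
    causal_idx <- sort(sample.int(M, config$n_causal))
    p_alt[causal_idx] <- runif(config$n_causal,
                               config$causal_freq_range[1],
                               config$causal_freq_range[2])
    effects <- if (is.null(config$effect_sizes))
      config$effect_decay^(seq_len(config$n_causal) - 1)
    else config$effect_sizes
  }

  if (!is.null(config$n_founder_haplotypes)) {
    n_pool <- config$n_founder_haplotypes
    pool <- matrix(rbinom(n_pool * M, 1L, rep(p_alt, each = n_pool)),
                   nrow = n_pool, ncol = M)
    # causal loci must segregate in the ancestral pool at their configured
    # frequency (a finite pool would otherwise lose rare alleles entirely)
    for (ci in seq_along(causal_idx)) {
      n_carry <- min(n_pool - 1L, max(1L, round(p_alt[causal_idx[ci]] * n_pool)))
      pool[, causal_idx[ci]] <- 0L
      pool[sample.int(n_pool, n_carry), causal_idx[ci]] <- 1L
    }
    block <- config$founder_block_bp %||% Inf
    if (is.infinite(block)) {
      H <- pool[sample.int(n_pool, 2L * N, replace = TRUE), , drop = FALSE]
    } else {
      # mosaic founders: each haplotype copies pool haplotypes in ancestry
      # blocks of exponential length, emulating historical recombination
      H <- matrix(0L, nrow = 2L * N, ncol = M)
      for (ch in unique(chrom)) {
        cols <- which(chrom == ch)
        cpos <- pos[cols]
        clen <- config$chrom_length_bp
        for (i in seq_len(2L * N)) {
          n_bk <- rpois(1L, clen / block)
          if (n_bk == 0L) {
            H[i, cols] <- pool[sample.int(n_pool, 1L), cols]
          } else {
            cuts <- sort(runif(n_bk, 0, clen))
            src <- sample.int(n_pool, n_bk + 1L, replace = TRUE)
            seg <- findInterval(cpos, cuts) + 1L
            H[i, cols] <- pool[cbind(src[seg], cols)]
          }
        }
      }
    }
  } else {
    H <- matrix(rbinom(2L * N * M, 1L, rep(p_alt, each = 2L * N)),
                nrow = 2L * N, ncol = M)
  }
  storage.mode(H) <- "integer"

  # calibrate the trait scale at the founders
  gv <- rep(0, N)
  if (length(causal_idx) && config$h2 > 0) {
    dos <- H[seq(1L, 2L * N, 2L), causal_idx, drop = FALSE] +
      H[seq(2L, 2L * N, 2L), causal_idx, drop = FALSE]
    raw <- as.vector(dos %*% effects)
    v <- var(raw)
    scale <- if (v > 0) sqrt(config$h2 * config$pheno_sd^2 / v) else 0
    effects <- effects * scale
    gv <- raw * scale
  } else {
    effects <- rep(0, length(effects))
  }
  sigma_e <- sqrt(1 - config$h2) * config$pheno_sd
  offset <- config$pheno_mean - mean(gv)

  pop <- list(
    haplotypes = H,
    sex = sample(rep(c("M", "F"), length.out = N)),
    genetic_value = gv,
    phenotype = offset + gv + rnorm(N, 0, sigma_e),
    generation = 1L,
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    causal = data.frame(index = causal_idx, effect = effects),
    sigma_e = sigma_e,
    pheno_offset = offset,
    chrom_lengths = setNames(rep(config$chrom_length_bp, K),
                             sprintf("chr%d", seq_len(K)))
  )
  class(pop) <- "population"
  pop
}

#' Parents retained by phenotypic truncation
#'
#' Ranks each sex by phenotype (descending) and keeps the top
#' `ceiling(retention * N_sex)` individuals.
#'
#' @param pop A `population`.
#' @param config A [sim_config()].
#' @return List with integer indices `dams` and `sires`.
#' @export
retained_parents <- function(pop, config) {
  keep_top <- function(idx, frac) {
    n_keep <- as.integer(ceiling(frac * length(idx)))
    idx[order(pop$phenotype[idx], decreasing = TRUE)][seq_len(n_keep)]
  }
  dams <- keep_top(which(pop$sex == "F"), config$female_retention)
  sires <- keep_top(which(pop$sex == "M"), config$male_retention)
  if (length(dams) < 2L || length(sires) < 2L)
    stop("selection collapse: fewer than 2 retained parents of one sex",
         call. = FALSE)
  list(dams = dams, sires = sires)
}

# Build all gametes contributed by `parent_of` (one parent index per
# offspring) for one chromosome block. Zero-crossover gametes (the vast
# majority at realistic rates) are copied as whole rows; gametes with
# crossovers are assembled per segment.
make_gametes <- function(H, parent_of, site_cols, site_pos, chrom_len, rate) {
  n <- length(parent_of)
  n_xo <- rpois(n, rate * chrom_len)
  start_hap <- sample.int(2L, n, replace = TRUE) # 1 or 2
  out <- matrix(0L, nrow = n, ncol = length(site_cols))
  plain <- which(n_xo == 0L)
  if (length(plain)) {
    rows <- 2L * (parent_of[plain] - 1L) + start_hap[plain]
    out[plain, ] <- H[rows, site_cols, drop = FALSE]
  }
  for (i in which(n_xo > 0L)) {
    xo <- sort(runif(n_xo[i], 0, chrom_len))
    seg <- findInterval(site_pos, xo)          # crossovers upstream of site
    hap <- 1L + (start_hap[i] - 1L + seg) %% 2L
    rows <- 2L * (parent_of[i] - 1L) + hap
    out[i, ] <- H[cbind(rows, site_cols)]
  }
  out
}

#' Advance the population by one generation of truncation selection
#'
#' Retains the top fraction of each sex by phenotype, then forms
#' `config$pop_size` offspring by drawing a dam and a sire uniformly with
#' replacement from the retained sets (selfing is impossible since parents
#' are of opposite sex). Each transmitted gamete undergoes a Poisson number
#' of crossovers per chromosome at uniform positions. Offspring phenotypes
#' add Gaussian noise with the environmental standard deviation fixed at the
#' founder generation.
#'
#' @inheritParams retained_parents
#' @return The next `population` (generation incremented).
#' @export
advance_generation <- function(pop, config) {
  par <- retained_parents(pop, config)
  N <- config$pop_size
  dam_of <- sample(par$dams, N, replace = TRUE)
  sire_of <- sample(par$sires, N, replace = TRUE)

  M <- ncol(pop$haplotypes)
  H_new <- matrix(0L, nrow = 2L * N, ncol = M)
  mat_rows <- seq(1L, 2L * N, 2L)
  for (ch in unique(pop$sites$chrom)) {
    cols <- which(pop$sites$chrom == ch)
    cl <- pop$chrom_lengths[[ch]]
    H_new[mat_rows, cols] <- make_gametes(pop$haplotypes, dam_of, cols,
                                          pop$sites$pos[cols], cl,
                                          config$recomb_rate)
    H_new[mat_rows + 1L, cols] <- make_gametes(pop$haplotypes, sire_of, cols,
                                               pop$sites$pos[cols], cl,
                                               config$recomb_rate)
  }

  gv <- rep(0, N)
  if (nrow(pop$causal)) {
    ci <- pop$causal$index
    dos <- H_new[mat_rows, ci, drop = FALSE] + H_new[mat_rows + 1L, ci, drop = FALSE]
    gv <- as.vector(dos %*% pop$causal$effect)
  }
  out <- pop
  out$haplotypes <- H_new
  out$sex <- sample(rep(c("M", "F"), length.out = N))
  out$genetic_value <- gv
  out$phenotype <- pop$pheno_offset + gv + rnorm(N, 0, pop$sigma_e)
  out$generation <- pop$generation + 1L
  out
}

#' Run the full breeding simulation
#'
#' Simulates founders and advances them through `n_generations` of
#' truncation selection, keeping every generation.
#'
#' @param config A [sim_config()]. If `config$seed` is set, the RNG is
#'   seeded here so identical configs give bit-identical runs.
#' @return A `breeding_sim` object: list with `populations` (one
#'   `population` per generation, 1-indexed) and `config`.
#' @export
run_breeding_simulation <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pops <- vector("list", config$n_generations)
  pops[[1L]] <- simulate_founders(config)
  for (g in seq_len(config$n_generations - 1L))
    pops[[g + 1L]] <- advance_generation(pops[[g]], config)
  structure(list(populations = pops, config = config), class = "breeding_sim")
}

#' @export
print.breeding_sim <- function(x, ...) {
  means <- vapply(x$populations, function(p) mean(p$phenotype), 0)
  cat(sprintf("<breeding_sim> %d generations of %d individuals; mean phenotype %.1f -> %.1f g\n",
              length(x$populations), x$config$pop_size,
              means[1], means[length(means)]))
  invisible(x)
}

#' Sample sequenced cohorts from a simulated line
#'
#' Draws the scheduled numbers of males and females per generation uniformly
#' without replacement, then removes `drop_samples` random individuals from
#' the indicated generations (emulating lost samples). With the default
#' schedule and drop this yields 119 samples. Genotypes are returned as a
#' [variant_table] (phased), together with sample metadata and phenotype
#' records in which breast measurements are back-filled from the simulated
#' BMW (BB = KL = 10 cm reference; BMT = BMV / (BB*KL)).
#'
#' @param sim A `breeding_sim`.
#' @param schedule Data frame `generation`, `n_males`, `n_females`; defaults
#'   to the simulation config's schedule.
#' @param drop_samples Data frame `generation`, `n`; defaults to the config's.
#' @return List with `genotypes` (a `variant_table`), `meta`
#'   (`sample_id`, `generation`, `sex`) and `phenotypes`
#'   (`sample_id`, `BB`, `KL`, `BMT`, `BMV`, `BMW`, `sex`, `generation`).
#' @export
sample_cohorts <- function(sim, schedule = NULL, drop_samples = NULL) {
  if (is.null(schedule)) schedule <- sim$config$sample_schedule
  if (is.null(drop_samples)) drop_samples <- sim$config$drop_samples

  picks <- list()
  for (r in seq_len(nrow(schedule))) {
    g <- schedule$generation[r]
    if (g < 1L || g > length(sim$populations))
      stop("schedule error: generation ", g, " was not simulated", call. = FALSE)
    pop <- sim$populations[[g]]
    take <- function(sex, n) {
      avail <- which(pop$sex == sex)
      if (n > length(avail))
        stop("schedule error: requested ", n, " ", sex,
             " samples in generation ", g, " but only ", length(avail),
             " exist", call. = FALSE)
      sort(sample(avail, n))
    }
    idx <- c(take("M", schedule$n_males[r]), take("F", schedule$n_females[r]))
    if (length(idx))
      picks[[length(picks) + 1L]] <- data.frame(generation = g, index = idx)
  }
  picks <- if (length(picks)) do.call(rbind, picks) else
    data.frame(generation = integer(0), index = integer(0))

  if (!is.null(drop_samples) && nrow(picks)) {
    for (r in seq_len(nrow(drop_samples))) {
      g <- drop_samples$generation[r]
      cand <- which(picks$generation == g)
      n_drop <- min(drop_samples$n[r], length(cand))
      if (n_drop > 0) picks <- picks[-sample(cand, n_drop), , drop = FALSE]
    }
  }

  n <- nrow(picks)
  sites <- sim$populations[[1L]]$sites
  hap <- matrix(0L, nrow = nrow(sites), ncol = 2L * n)
  sex <- character(n)
  bmw <- numeric(n)
  ids <- character(n)
  counter <- integer(max(c(picks$generation, 1L)))
  for (i in seq_len(n)) {
    g <- picks$generation[i]
    ind <- picks$index[i]
    pop <- sim$populations[[g]]
    hap[, 2L * i - 1L] <- pop$haplotypes[2L * ind - 1L, ]
    hap[, 2L * i] <- pop$haplotypes[2L * ind, ]
    sex[i] <- pop$sex[ind]
    bmw[i] <- pop$phenotype[ind]
    counter[g] <- counter[g] + 1L
    ids[i] <- sprintf("G%02d_%s%03d", g, sex[i], counter[g])
  }
  odd <- 2L * seq_len(n) - 1L
  dosage <- hap[, odd, drop = FALSE] + hap[, odd + 1L, drop = FALSE]
  colnames(dosage) <- ids
  vt <- new_variant_table(sites, dosage, haplotypes = hap, samples = ids,
                          phased = TRUE)

  meta <- data.frame(sample_id = ids, generation = picks$generation, sex = sex,
                     stringsAsFactors = FALSE)
  bmv <- pmax(bmw - .bmw_intercept, 1) / .bmw_slope
  bb <- kl <- rep(10, n)
  pheno <- data.frame(sample_id = ids, BB = bb, KL = kl, BMT = bmv / (bb * kl),
                      BMV = bmv, BMW = bmw, sex = sex,
                      generation = picks$generation, stringsAsFactors = FALSE)
  list(genotypes = vt, meta = meta, phenotypes = pheno)
}

#' Export ground truth from a simulated line
#'
#' @param sim A `breeding_sim`.
#' @return List with `trajectories` (a `n_snps x n_generations` matrix of
#'   true ALT-allele frequencies in the full population) and `causal` (the
#'   causal-locus registry: site index, chrom, pos, effect).
#' @export
export_truth <- function(sim) {
  traj <- vapply(sim$populations, function(p) colMeans(p$haplotypes),
                 numeric(ncol(sim$populations[[1L]]$haplotypes)))
  colnames(traj) <- paste0("G", seq_along(sim$populations))
  causal <- sim$populations[[1L]]$causal
  sites <- sim$populations[[1L]]$sites
  if (nrow(causal)) {
    causal$chrom <- sites$chrom[causal$index]
    causal$pos <- sites$pos[causal$index]
  } else {
    causal$chrom <- character(0)
    causal$pos <- integer(0)
  }
  list(trajectories = traj, causal = causal)
}

#' Simulate a normalized copy-number matrix for sampled cohorts
#'
#' Emulates the output of a read-depth CNV caller on the sequenced cohorts:
#' each CNV region (CNVR) is a deletion, duplication or multicopy locus with
#' a carrier (non-diploid-normal) frequency; per-sample copy-number classes
#' are drawn under Hardy-Weinberg from the carrier-allele frequency and
#' observed with Gaussian measurement noise. Neutral CNVRs keep a constant
#' carrier frequency across generations; `selected` CNVRs interpolate their
#' carrier frequency linearly from generation 1 to `n_generations`.
#'
#' @param meta Sample metadata (`sample_id`, `generation`).
#' @param n_cnvr Number of CNVRs (the emulated study retained 81).
#' @param selected Data frame `type` ("del", "dup", "multi"), `f_start`,
#'   `f_end` (carrier frequencies at the first and last generation). The
#'   default mirrors the emulated study's finding of two duplications and
#'   one deletion with strong frequency shifts.
#' @param n_generations Last generation (for interpolation).
#' @param chrom_lengths Named vector used to place CNVR coordinates.
#' @param noise_sd Measurement noise on the normalized copy number.
#' @param neutral_freq_range Carrier-frequency range of neutral CNVRs.
#' @return List with `values` (CNVR x sample numeric matrix), `cnvrs`
#'   (id, chrom, start, end, type, selected flag) and `truth` (carrier
#'   frequency per CNVR per generation used to generate the data).
#' @export
simulate_cnv_matrix <- function(meta, n_cnvr = 81L,
                                selected = data.frame(
                                  type = c("dup", "dup", "del"),
                                  f_start = c(0.15, 0.20, 0.35),
                                  f_end = c(0.65, 0.60, 0.80)),
                                n_generations = 10L,
                                chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                                noise_sd = 0.08,
                                neutral_freq_range = c(0.05, 0.5)) {
  n_sel <- if (is.null(selected)) 0L else nrow(selected)
  stopifnot(n_sel <= n_cnvr)
  type <- c(as.character(selected$type),
            sample(c("del", "dup", "multi"), n_cnvr - n_sel, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2)))
  f0 <- c(selected$f_start,
          runif(n_cnvr - n_sel, neutral_freq_range[1], neutral_freq_range[2]))
  f1 <- c(selected$f_end, f0[seq_len(n_cnvr - n_sel) + n_sel])
  is_sel <- seq_len(n_cnvr) <= n_sel

  gens <- sort(unique(meta$generation))
  f_at <- function(i, g) {
    w <- if (n_generations > 1) (g - 1) / (n_generations - 1) else 0
    (1 - w) * f0[i] + w * f1[i]
  }
  n <- nrow(meta)
  values <- matrix(0, n_cnvr, n, dimnames = list(NULL, meta$sample_id))
  truth <- matrix(0, n_cnvr, length(gens),
                  dimnames = list(NULL, paste0("G", gens)))
  for (i in seq_len(n_cnvr)) {
    for (gi in seq_along(gens)) {
      g <- gens[gi]
      f <- f_at(i, g)
      truth[i, gi] <- f
      q <- 1 - sqrt(1 - min(f, 0.999))       # carrier-allele frequency
      cols <- which(meta$generation == g)
      cn_alleles <- rbinom(length(cols), 2L, q)
      cls <- switch(type[i],
        del = 1 - 0.5 * cn_alleles,
        dup = 1 + 0.5 * cn_alleles,
        multi = 1 + cn_alleles)
      values[i, cols] <- cls + rnorm(length(cols), 0, noise_sd)
    }
  }
  values[values < 0] <- 0
  chrom <- sample(names(chrom_lengths), n_cnvr, replace = TRUE)
  start <- floor(runif(n_cnvr, 0, chrom_lengths[chrom] * 0.9))
  width <- floor(runif(n_cnvr, 5e3, 2e5))
  cnvrs <- data.frame(cnvr_id = sprintf("CNVR%03d", seq_len(n_cnvr)),
                      chrom = chrom, start = start, end = start + width,
                      type = type, selected = is_sel,
                      stringsAsFactors = FALSE)
  rownames(values) <- cnvrs$cnvr_id
  rownames(truth) <- cnvrs$cnvr_id
  list(values = values, cnvrs = cnvrs, truth = truth)
}

#' Generate a toy annotation track along simulated chromosomes
#'
#' Tiles simple gene models (5'UTR, three exons separated by introns, 3'UTR)
#' at regular intervals along each chromosome; everything else is implicitly
#' intergenic. Coordinates are 0-based half-open, as in BED.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param gene_spacing Distance between successive gene starts, bp.
#' @return Data frame `chrom`, `start`, `end`, `category` with categories
#'   `exon`, `intron`, `UTR`.
#' @export
make_annotation_track <- function(chrom_lengths, gene_spacing = 50000) {
  block <- data.frame(
    offset = c(0, 300, 600, 2100, 2400, 3900, 4200, 4500),
    width = c(300, 300, 1500, 300, 1500, 300, 300, NA),
    category = c("UTR", "exon", "intron", "exon", "intron", "exon", "UTR", NA)
  )[1:7, ]
  out <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(10000, chrom_lengths[[ch]] - 5000, by = gene_spacing)
    for (s in starts) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s + block$offset, end = s + block$offset + block$width,
        category = block$category, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
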