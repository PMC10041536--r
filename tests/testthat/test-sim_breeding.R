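test_that("breast muscle weight formula matches the measurement regression", {
  expect_equal(bmw_from_measurements(0, 0, 0), 17.042)
  expect_equal(bmw_from_measurements(1, 1, 1), 17.6648)
  expect_equal(bmw_from_measurements(10, 10, 2), 141.602)
  expect_error(bmw_from_measurements(-1, 2, 2), "invalid measurement")
  expect_error(bmw_from_measurements(Inf, 2, 2), "invalid measurement")
})

test_that("founder allele frequencies follow the configured law", {
  set.seed(1)
  cfg <- sim_config(pop_size = 500L, n_snps = 1000L, n_causal = 0L,
                    founder_maf_law = list(dist = "fixed", value = 0.5),
                    n_founder_haplotypes = NULL)
  pop <- simulate_founders(cfg)
  freqs <- colMeans(pop$haplotypes)
  # mean over 1000 loci of binomial(2N, 0.5) frequencies
  se <- sqrt(0.25 / (2 * cfg$pop_size) / cfg$n_snps)
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
  expect_true(all(pop$genetic_value == 0))
})

test_that("identical seeds give bitwise-identical simulations", {
  cfg <- test_sim_config(seed = 42L)
  s1 <- run_breeding_simulation(cfg)
  s2 <- run_breeding_simulation(cfg)
  expect_identical(s1$populations[[6]]$haplotypes,
                   s2$populations[[6]]$haplotypes)
  expect_identical(s1$populations[[6]]$phenotype,
                   s2$populations[[6]]$phenotype)
  set.seed(9); c1 <- sample_cohorts(s1)
  set.seed(9); c2 <- sample_cohorts(s2)
  expect_identical(c1$meta$sample_id, c2$meta$sample_id)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
})

test_that("truncation retains the ceiling of the retention fraction per sex", {
  set.seed(2)
  cfg <- sim_config(pop_size = 750L, n_snps = 50L, n_causal = 0L)
  pop <- simulate_founders(cfg)
  # force exactly 375 of each sex
  pop$sex <- rep(c("M", "F"), length.out = 750L)
  par <- retained_parents(pop, cfg)
  expect_length(par$sires, ceiling(0.075 * 375))   # 29 sires
  expect_length(par$dams, ceiling(0.375 * 375))    # 141 dams
  expect_length(par$sires, 29L)
  # retained sires have the top phenotypes among males
  males <- which(pop$sex == "M")
  expect_setequal(par$sires,
                  males[order(pop$phenotype[males], decreasing = TRUE)][1:29])
  expect_error(retained_parents(list(sex = rep("M", 10), phenotype = 1:10),
                                cfg),
               "selection collapse")
})

test_that("dosage equals haplotype sum after transmission", {
  set.seed(3)
  cfg <- test_sim_config()
  sim <- run_breeding_simulation(cfg)
  co <- sample_cohorts(sim)
  vt <- co$genotypes
  n <- n_samples(vt)
  hsum <- vt$haplotypes[, seq(1, 2 * n, 2)] + vt$haplotypes[, seq(2, 2 * n, 2)]
  expect_identical(unname(hsum), unname(vt$dosage))
  # genetic value equals dosage %*% effects at every generation
  pop <- sim$populations[[4]]
  dos <- pop$haplotypes[seq(1, nrow(pop$haplotypes), 2), pop$causal$index] +
    pop$haplotypes[seq(2, nrow(pop$haplotypes), 2), pop$causal$index]
  expect_equal(as.vector(dos %*% pop$causal$effect), pop$genetic_value)
})

test_that("zero heritability yields no selection response", {
  set.seed(4)
  slopes <- replicate(15, {
    cfg <- sim_config(pop_size = 150L, n_generations = 8L,
                      n_chromosomes = 1L, chrom_length_bp = 1e6,
                      n_snps = 120L, n_causal = 5L, h2 = 0,
                      n_founder_haplotypes = 16L)
    sim <- run_breeding_simulation(cfg)
    means <- vapply(sim$populations, function(p) mean(p$phenotype), 0)
    unname(coef(lm(means ~ seq_along(means)))[2])
  })
  tstat <- mean(slopes) / (sd(slopes) / sqrt(length(slopes)))
  expect_lt(tstat, 3)   # slope not significantly positive
})

test_that("selection shifts causal allele frequencies more than neutral ones", {
  set.seed(5)
  diffs <- replicate(10, {
    cfg <- test_sim_config()
    sim <- run_breeding_simulation(cfg)
    tr <- export_truth(sim)
    d <- abs(tr$trajectories[, ncol(tr$trajectories)] - tr$trajectories[, 1])
    mean(d[tr$causal$index]) - mean(d[-tr$causal$index])
  })
  expect_gt(mean(diffs > 0), 0.7)
  expect_gt(mean(diffs), 0)
})

test_that("default cohort schedule yields 119 samples with one lost at G4", {
  set.seed(6)
  cfg <- sim_config(n_snps = 100L, n_causal = 0L)
  sim <- run_breeding_simulation(cfg)
  co <- sample_cohorts(sim)
  expect_equal(nrow(co$meta), 119L)
  expect_equal(as.vector(table(co$meta$generation)), c(30L, 29L, 30L, 30L))
  expect_equal(n_samples(co$genotypes), 119L)
  # phenotype identity BMV = BB x KL x BMT and the BMW regression hold
  with(co$phenotypes, {
    expect_equal(BMV, BB * KL * BMT)
    expect_equal(BMW[BMW > 18], 0.6228 * BMV[BMW > 18] + 17.042)
  })
})

test_that("empty cohorts and bad schedules are handled", {
  set.seed(7)
  cfg <- test_sim_config()
  sim <- run_breeding_simulation(cfg)
  empty <- sample_cohorts(sim, schedule = data.frame(generation = 1L,
                                                     n_males = 0L,
                                                     n_females = 0L),
                          drop_samples = NULL)
  expect_equal(nrow(empty$meta), 0L)
  expect_error(sample_cohorts(sim,
                              schedule = data.frame(generation = 99L,
                                                    n_males = 1L,
                                                    n_females = 1L)),
               "schedule error")
  expect_error(sample_cohorts(sim,
                              schedule = data.frame(generation = 1L,
                                                    n_males = 1000L,
                                                    n_females = 1L)),
               "schedule error")
})

test_that("export_truth reports flat trajectories for monomorphic loci", {
  set.seed(8)
  cfg <- test_sim_config()
  sim <- run_breeding_simulation(cfg)
  # force a monomorphic locus in the founders and re-run transmission
  tr <- export_truth(sim)
  fixed <- which(tr$trajectories[, 1] %in% c(0, 1))
  if (length(fixed)) {
    expect_true(all(tr$trajectories[fixed, ] ==
                      tr$trajectories[fixed, 1]))
  }
  # no deterministic sweep from interior frequencies in a neutral run
  expect_true(all(tr$trajectories >= 0 & tr$trajectories <= 1))
})

test_that("neutral drift variance matches the unequal-sex-number Ne", {
  set.seed(11)
  cfg <- sim_config(pop_size = 400L, n_generations = 6L,
                    n_chromosomes = 1L, chrom_length_bp = 1e6,
                    n_snps = 250L, n_causal = 0L,
                    n_founder_haplotypes = NULL,
                    founder_maf_law = list(dist = "uniform", min = 0.3, max = 0.7))
  sim <- run_breeding_simulation(cfg)
  tr <- export_truth(sim)$trajectories
  nm <- ceiling(cfg$male_retention * 200)
  nf <- ceiling(cfg$female_retention * 200)
  ne <- 4 * nm * nf / (nm + nf)
  x2 <- c()
  for (g in seq_len(ncol(tr) - 1)) {
    p <- tr[, g]
    ok <- p > 0.1 & p < 0.9
    x2 <- c(x2, ((tr[ok, g + 1] - p[ok])^2) / (p[ok] * (1 - p[ok])))
  }
  ratio <- mean(x2) * 2 * ne
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.35)
})

test_that("simulated CNV matrix has shifting selected and stable neutral loci", {
  set.seed(12)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:120),
                     generation = rep(c(1, 4, 7, 10), each = 30))
  cn <- simulate_cnv_matrix(meta, n_cnvr = 40L)
  expect_equal(dim(cn$values), c(40L, 120L))
  expect_true(all(cn$values >= 0))
  expect_equal(sum(cn$cnvrs$selected), 3L)
  # selected truth frequencies rise; neutral stay flat
  sel <- which(cn$cnvrs$selected)
  expect_true(all(cn$truth[sel, "G10"] > cn$truth[sel, "G1"]))
  neu <- which(!cn$cnvrs$selected)
  expect_true(all(cn$truth[neu, "G10"] == cn$truth[neu, "G1"]))
})
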