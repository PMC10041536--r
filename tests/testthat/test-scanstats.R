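test_that("site Fst hits the boundary cases", {
  # complete differentiation: fixed REF vs fixed ALT, no heterozygotes
  a <- matrix(rep(0L, 20), nrow = 1)
  b <- matrix(rep(2L, 20), nrow = 1)
  res <- wc_fst_site(a, b)
  expect_equal(res$fst, 1)
  # identical genotype vectors: no between-population variance signal
  # (the unbiased estimator centres such sites at <= 0, not exactly 0)
  g <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L), nrow = 1)
  res2 <- wc_fst_site(g, g)
  expect_lte(res2$a, 0)
  expect_lte(res2$fst, 0)
  expect_lt(abs(res2$fst), 0.2)
  # monomorphic across both cohorts: components (0, 0), uninformative
  mono <- wc_fst_site(matrix(0L, 1, 6), matrix(0L, 1, 6))
  expect_equal(mono$a, 0)
  expect_equal(mono$d, 0)
  expect_false(mono$informative)
  expect_true(is.na(mono$fst))
})

test_that("site Fst components match the brute-force estimator on random instances", {
  set.seed(41)
  for (i in 1:120) {
    na <- sample(4:25, 1); nb <- sample(4:25, 1)
    ga <- rbinom(na, 2, runif(1, 0.1, 0.9))
    gb <- rbinom(nb, 2, runif(1, 0.1, 0.9))
    if (sum(ga) + sum(gb) == 0 || sum(ga) + sum(gb) == 2 * (na + nb)) next
    res <- wc_fst_site(matrix(ga, 1), matrix(gb, 1))
    ora <- wc84_oracle(ga, gb)
    expect_equal(res$a, ora$a, tolerance = 1e-12)
    expect_equal(res$d, ora$d, tolerance = 1e-12)
  }
  # the worked 6-vs-6 case from the estimator definition
  ga <- c(0L, 0L, 1L, 1L, 2L, 2L); gb <- rep(0L, 6)
  res <- wc_fst_site(matrix(ga, 1), matrix(gb, 1))
  ora <- wc84_oracle(ga, gb)
  expect_equal(res$a / res$d, ora$a / ora$d, tolerance = 1e-12)
})

test_that("windowed Fst is the ratio of sums over member sites", {
  sites <- data.frame(chrom = "chr1", pos = c(1000, 4000, 8000))
  comp <- data.frame(a = c(0.1, 0.2, 0.05), d = c(0.5, 0.4, 0.2),
                     informative = TRUE)
  comp$fst <- comp$a / comp$d
  win <- fst_windows(sites, comp, window = 10000, step = 5000,
                     chrom_lengths = c(chr1 = 10000))
  expect_equal(win$value, sum(comp$a) / sum(comp$d))
  expect_equal(win$n_snps, 3L)
  # identical components per site: window value equals site value
  comp2 <- data.frame(a = rep(0.1, 3), d = rep(0.4, 3), fst = 0.25,
                       informative = TRUE)
  win2 <- fst_windows(sites, comp2, 10000, 5000, c(chr1 = 10000))
  expect_equal(win2$value, 0.25)
  # mean-of-sites alternative
  win3 <- fst_windows(sites, comp, 10000, 5000, c(chr1 = 10000),
                      mean_of_sites = TRUE)
  expect_equal(win3$value, mean(comp$a / comp$d))
})

test_that("window tiling follows the 10k/5k convention", {
  w <- make_windows(c(chr1 = 25000), window = 10000, step = 5000)
  expect_equal(w$start, c(0, 5000, 10000, 15000))
  expect_equal(w$end, c(10000, 15000, 20000, 25000))
  expect_error(make_windows(c(chr1 = 25000), window = 5000, step = 10000),
               "config error")
  # short chromosome yields one covering window
  w2 <- make_windows(c(chr1 = 8000), 10000, 5000)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$end, 8000)
})

test_that("EHH is 1 at the core, combinatorial at splits, and monotone", {
  pos <- seq(100, by = 100, length.out = 9)
  # all carriers share one haplotype: EHH = 1 everywhere
  hap1 <- matrix(rep(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), each = 4), nrow = 4)
  e1 <- ehh(hap1, pos, core = 5)
  expect_true(all(e1$ehh == 1))
  # 4 carriers splitting 2+2 one step right: EHH = 2 / C(4,2) = 1/3
  hap2 <- matrix(0L, nrow = 4, ncol = 9)
  hap2[3:4, 6] <- 1L
  e2 <- ehh(hap2, pos, core = 5, core_allele = 0L)
  expect_equal(e2$ehh[e2$index == 6], 1 / 3)
  # monotone non-increasing on random input, and matches the string oracle
  set.seed(42)
  for (rep in 1:20) {
    hap <- matrix(rbinom(8 * 15, 1L, 0.5), nrow = 8)
    core <- sample(3:13, 1)
    e <- ehh(hap, seq_len(15) * 50, core, cutoff = 0)
    right <- e$ehh[e$index >= core]
    left <- rev(e$ehh[e$index <= core])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
    ora <- ehh_oracle_side(hap, core, 1:8, dir = 1, cutoff = 0)
    expect_equal(e$ehh[e$index > core], ora, tolerance = 1e-12)
  }
  expect_error(ehh(matrix(c(0L, NA), 2, 2), c(1, 2), 1), "phase required")
})

test_that("iHH matches the trapezoid oracle and XP-EHH is antisymmetric", {
  set.seed(43)
  pos <- sort(sample(1:5000, 30))
  for (rep in 1:15) {
    hap <- matrix(rbinom(8 * 30, 1L, runif(30, 0.2, 0.8)[rep(1:30, each = 8)]),
                  nrow = 8)
    core <- sample(5:25, 1)
    expect_equal(ihh(hap, pos, core), ihh_oracle(hap, pos, core),
                 tolerance = 1e-10)
  }
  hapA <- matrix(rbinom(8 * 30, 1L, 0.5), nrow = 8)
  hapB <- matrix(rbinom(8 * 30, 1L, 0.5), nrow = 8)
  fwd <- xpehh(hapA, hapB, pos)
  rev_ <- xpehh(hapB, hapA, pos)
  expect_equal(fwd$xpehh, -rev_$xpehh, tolerance = 1e-12)
  # identical cohorts: all unstandardized values are exactly zero
  same <- xpehh(hapA, hapA, pos)
  expect_true(all(same$xpehh[!same$skipped] == 0))
})

test_that("empirical thresholds use type-7 quantiles", {
  expect_equal(suppressWarnings(empirical_threshold(1:100, 0.01))[["upper"]],
               99.01)
  expect_equal(suppressWarnings(empirical_threshold(rep(7, 50), 0.01))[["upper"]],
               7)
  two <- suppressWarnings(empirical_threshold(-50:50, 0.05, side = "two"))
  expect_equal(unname(two[["upper"]] + two[["lower"]]), 0)  # symmetric about 0
  expect_error(empirical_threshold(numeric(0)), "empty")
  expect_warning(empirical_threshold(1:50, 0.01), "noisy")
})

test_that("candidate-window intersection merges correctly", {
  f <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(10000, 15000))
  x <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  reg <- intersect_candidate_windows(f, x)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(10000, 15000))
  # disjoint sets: nothing
  expect_equal(nrow(intersect_candidate_windows(
    data.frame(chrom = "chr1", start = 0, end = 1000),
    data.frame(chrom = "chr1", start = 5000, end = 6000))), 0L)
  # identical sets: merged windows
  reg2 <- intersect_candidate_windows(f, f)
  expect_equal(nrow(reg2), 1L)
  expect_equal(c(reg2$start, reg2$end), c(0, 15000))
  # different chromosomes never intersect
  expect_equal(nrow(intersect_candidate_windows(
    f, transform(x, chrom = "chr2"))), 0L)
})

test_that("nucleotide diversity matches the all-pairs oracle", {
  # 2 haplotypes differing at 3 sites in a 10-kb window
  hap <- rbind(rep(0L, 5), c(1L, 1L, 1L, 0L, 0L))
  sites <- data.frame(chrom = "chr1", pos = c(500, 2000, 4000, 6000, 9000))
  pw <- nucleotide_diversity(hap, sites, window = 10000, step = 10000,
                             chrom_lengths = c(chr1 = 10000))
  expect_equal(pw$value, 3 / 10000)
  # identical haplotypes: pi = 0
  pw0 <- nucleotide_diversity(rbind(rep(0L, 5), rep(0L, 5)), sites,
                              10000, 10000, c(chr1 = 10000))
  expect_equal(pw0$value, 0)
  # brute force, 10 haplotypes x 50 sites
  set.seed(44)
  hap2 <- matrix(rbinom(10 * 50, 1L, 0.4), nrow = 10)
  sites2 <- data.frame(chrom = "chr1", pos = sort(sample(1:9999, 50)))
  pw2 <- nucleotide_diversity(hap2, sites2, 10000, 10000,
                              c(chr1 = 10000))
  expect_equal(pw2$value, pi_oracle(hap2, 10000), tolerance = 1e-12)
  # empty window flagged with zero sites
  pw3 <- nucleotide_diversity(hap2, sites2, 10000, 10000,
                              c(chr1 = 30000))
  expect_equal(pw3$n_snps[3], 0L)
  expect_equal(pw3$value[3], 0)
})

test_that("genotype PCA is orthonormal and separates drifted cohorts", {
  set.seed(45)
  dos <- random_dosage(200, 30)
  pc <- genotype_pca(dos, k = 3)
  expect_equal(unname(crossprod(pc$scores)), diag(3), tolerance = 1e-10)
  # duplicated sample lands on coincident coordinates
  dos2 <- cbind(dos, dos[, 1])
  pc2 <- genotype_pca(dos2, k = 2)
  expect_equal(pc2$scores[1, ], pc2$scores[31, ], tolerance = 1e-8)
  # two cohorts with modest differentiation separate on PC1
  p <- runif(300, 0.2, 0.8)
  shift <- pmin(pmax(p + rnorm(300, 0, 0.12), 0.02), 0.98)
  da <- sapply(p, function(q) rbinom(25, 2, q))
  db <- sapply(shift, function(q) rbinom(25, 2, q))
  pc3 <- genotype_pca(t(rbind(da, db)), k = 2)
  grp <- rep(c(1, 2), each = 25)
  obs <- abs(diff(tapply(pc3$scores[, 1], grp, mean)))
  perm <- replicate(200, {
    g <- sample(grp)
    abs(diff(tapply(pc3$scores[, 1], g, mean)))
  })
  expect_lt(mean(perm >= obs), 0.05)
})

test_that("frequency trajectories count alleles correctly", {
  dos <- rbind(c(2L, 2L, 1L, 0L, 0L, 0L),
               c(0L, 0L, 0L, 0L, 0L, 0L))
  vt <- toy_vt(dos)
  meta <- data.frame(sample_id = vt$samples,
                     generation = rep(c(1L, 10L), each = 3))
  tr <- frequency_trajectory(vt, meta)
  # site 1 G1: alt alleles 2+2+1 of 6 -> ref 1/6; G10: ref 1
  expect_equal(tr$ref_af[tr$index == 1 & tr$generation == 1], 1 / 6)
  expect_equal(tr$ref_af[tr$index == 1 & tr$generation == 10], 1)
  expect_true(all(tr$ref_af[tr$index == 2] == 1))  # fixed: flat at 1
  expect_equal(unique(tr$n_alleles), 6L)
})

test_that("dN/dS proportion is a plain count ratio", {
  expect_equal(dnds_proportion(rep(c("nonsynonymous", "synonymous"),
                                   c(10, 20)))$ratio, 0.5)
  expect_equal(dnds_proportion(rep(c("nonsynonymous", "synonymous"),
                                   c(7, 7)))$ratio, 1)
  expect_warning(res <- dnds_proportion(rep("nonsynonymous", 3)),
                 "undefined")
  expect_true(is.na(res$ratio))
  expect_error(dnds_proportion(c("weird")), "unknown effect label")
  # sampling calibration: labels drawn at N/S odds 0.8 recover the ratio
  set.seed(46)
  n <- 500
  lab <- ifelse(runif(n) < 0.8 / 1.8, "nonsynonymous", "synonymous")
  est <- dnds_proportion(lab)$ratio
  expect_lt(abs(est - 0.8), 0.15)
})
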