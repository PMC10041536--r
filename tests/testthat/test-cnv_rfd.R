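test_that("copy-number classification rounds to half-integer classes", {
  expect_equal(classify_copy_number(0.97), "1")
  expect_equal(classify_copy_number(1.48), "1.5")
  expect_equal(classify_copy_number(3.2), ">2")
  expect_equal(classify_copy_number(c(0.1, 0.6, 2.24, 2.6)),
               c("0", "0.5", "2", ">2"))
  expect_error(classify_copy_number(-0.1), "data error")
  m <- classify_copy_number(matrix(c(1.1, 0.4), 1, 2))
  expect_true(is.matrix(m))
})

test_that("silhouette filter separates tight and smeared clusters", {
  set.seed(71)
  tight <- pmax(c(rnorm(50, 1, 0.01), rnorm(50, 0.5, 0.01)), 0)
  res <- silhouette_filter(tight)
  expect_gt(res$silhouette, 0.9)
  expect_true(res$keep)
  smeared <- pmax(c(rnorm(50, 1, 0.5), rnorm(50, 0.5, 0.5)), 0)
  res2 <- silhouette_filter(smeared)
  expect_false(res2$keep)
  # a rare minor state fails the frequency rule regardless of silhouette
  rare <- c(rnorm(98, 1, 0.01), rnorm(2, 0.5, 0.01))
  res3 <- silhouette_filter(rare)
  expect_false(res3$keep)
  expect_equal(res3$reason, "low minor-state frequency")
  res4 <- silhouette_filter(rnorm(100, 1, 0.01))
  expect_equal(res4$reason, "monomorphic")
})

test_that("RFD matches the pooled-SE arithmetic and is antisymmetric", {
  expect_equal(rfd(0.2, 0.6, 30, 30), 0.4 / sqrt(0.4 * 0.6 * (2 / 30)))
  expect_equal(round(rfd(0.2, 0.6, 30, 30), 3), 3.162)
  expect_equal(rfd(0.3, 0.3, 30, 30), 0)
  expect_equal(rfd(0.3, 0.3, 30, 30, method = "relative"), 0)
  expect_equal(rfd(0.2, 0.6, 30, 30), -rfd(0.6, 0.2, 30, 30))
  expect_equal(rfd(0.2, 0.6, method = "relative"),
               -rfd(0.6, 0.2, method = "relative"))
  expect_true(is.na(rfd(0, 0, 30, 30)))   # pooled frequency 0: undefined
})

test_that("top-5% screen selects exactly 5 of 100 distinct values", {
  set.seed(72)
  vals <- sample(seq(0.1, 10, length.out = 100))
  scr <- screen_cnvrs(vals, 0.05)
  expect_equal(sum(scr$selected), 5L)
  expect_true(all(abs(vals[scr$selected]) >= scr$cutoff))
  # all-equal values: the tie rule keeps everything at the cutoff
  scr2 <- screen_cnvrs(rep(2.5, 40))
  expect_true(all(scr2$selected))
  expect_error(screen_cnvrs(numeric(0)), "empty input")
})

test_that("a strong simulated frequency shift is almost always selected", {
  set.seed(73)
  hits <- replicate(20, {
    meta <- data.frame(sample_id = sprintf("S%03d", 1:60),
                       generation = rep(c(1L, 10L), each = 30))
    cn <- simulate_cnv_matrix(meta, n_cnvr = 81L,
                              selected = data.frame(type = "dup",
                                                    f_start = 0.1,
                                                    f_end = 0.7))
    scr <- cnv_screen(cn$values, meta)
    scr$selected[1]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the screen's false-positive rate matches the nominal tail", {
  set.seed(74)
  fps <- replicate(15, {
    meta <- data.frame(sample_id = sprintf("S%03d", 1:60),
                       generation = rep(c(1L, 10L), each = 30))
    cn <- simulate_cnv_matrix(meta, n_cnvr = 60L, selected = NULL)
    scr <- cnv_screen(cn$values, meta)
    mean(scr$selected[scr$qc_pass])
  })
  expect_lt(abs(mean(fps) - 0.05), 0.03)
})

test_that("variance explained recovers a 2% CNV effect", {
  set.seed(75)
  # exact linearity gives R2 = 1
  cls <- rep(c("0", "1", "2"), each = 10)
  expect_equal(suppressWarnings(
    cnv_variance_explained(cls, rep(c(0, 5, 10), each = 10))), 1)
  expect_true(is.na(cnv_variance_explained(rep("1", 30), rnorm(30))))
  # null: R2 stays small
  r2_null <- replicate(30, {
    cls <- sample(c("1", "1.5", "2"), 200, replace = TRUE)
    cnv_variance_explained(cls, rnorm(200))
  })
  expect_gte(mean(r2_null < 0.05), 0.95)
  # 2% of variance: median estimate lands in [0.01, 0.03]
  r2_est <- replicate(50, {
    x <- rbinom(500, 2, 0.3)
    beta <- sqrt(0.02 / var(x))
    y <- beta * x + rnorm(500, 0, sqrt(0.98))
    cnv_variance_explained(classify_copy_number(1 + 0.5 * x), y)
  })
  expect_gte(median(r2_est), 0.01)
  expect_lte(median(r2_est), 0.03)
})

test_that("carrier-frequency trajectories count carriers per generation", {
  cls <- matrix(c("1", "1", "1.5", "1", "0.5", "1.5",
                  "1", "1", "1", "1", "1", "1"),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("CNVR1", "CNVR2"), sprintf("S%d", 1:6)))
  meta <- data.frame(sample_id = sprintf("S%d", 1:6),
                     generation = rep(c(1L, 10L), each = 3))
  tr <- cnv_frequency_trajectory(cls, meta)
  expect_equal(tr$carrier_freq[tr$cnvr == "CNVR1" & tr$generation == 1], 1 / 3)
  expect_equal(tr$carrier_freq[tr$cnvr == "CNVR1" & tr$generation == 10], 2 / 3)
  expect_true(all(tr$carrier_freq[tr$cnvr == "CNVR2"] == 0))
  # hand-count toy: 2 carriers of 6 in G1 vs 4 of 6 in G10
  cls2 <- matrix(rep(c("1.5", "1"), c(2, 4)), nrow = 1,
                 dimnames = list("X", sprintf("S%d", 1:6)))
  meta2 <- data.frame(sample_id = sprintf("S%d", 1:6), generation = 1L)
  expect_equal(cnv_frequency_trajectory(cls2, meta2)$carrier_freq, 1 / 3)
})

test_that("a selected CNVR's carrier trajectory rises in expectation", {
  set.seed(76)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:120),
                     generation = rep(c(1L, 4L, 7L, 10L), each = 30))
  ups <- replicate(10, {
    cn <- simulate_cnv_matrix(meta, n_cnvr = 5L,
                              selected = data.frame(type = "del",
                                                    f_start = 0.1,
                                                    f_end = 0.7))
    cls <- classify_copy_number(cn$values)
    tr <- cnv_frequency_trajectory(cls[1, , drop = FALSE], meta)
    cor(tr$generation, tr$carrier_freq, method = "spearman")
  })
  expect_gt(mean(ups > 0), 0.8)
})
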