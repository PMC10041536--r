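#' Reference-allele frequencies for a cohort
#'
#' @param vt A [variant_table][new_variant_table].
#' @param sample_ids Samples forming the cohort.
#' @return Data frame `chrom`, `pos`, `ref_af`, `n_alleles` (non-missing
#'   allele count).
#' @export
cohort_ref_freq <- function(vt, sample_ids) {
  fr <- site_frequencies(vt, samples = sample_ids)
  data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
             ref_af = fr$ref_af, n_alleles = 2L * fr$n_called,
             stringsAsFactors = FALSE)
}

#' Per-SNP allele-frequency difference between two cohorts
#'
#' Computes `delta_af = |RefAF_B - RefAF_A|` per site, the temporal
#' allele-frequency shift between (by convention) the first and last
#' sampled generation. Sites monomorphic for the same allele in both
#' cohorts are flagged uninformative.
#'
#' @param freq_a,freq_b Cohort frequency tables from [cohort_ref_freq()]
#'   over the same site set.
#' @return Data frame `chrom`, `pos`, `ref_af_a`, `ref_af_b`, `delta_af`,
#'   `informative`.
#' @export
delta_af <- function(freq_a, freq_b) {
  if (nrow(freq_a) != nrow(freq_b) ||
      !all(freq_a$chrom == freq_b$chrom & freq_a$pos == freq_b$pos))
    stop("alignment error: cohort frequency tables cover different sites",
         call. = FALSE)
  mono <- (freq_a$ref_af %in% c(0, 1)) & freq_a$ref_af == freq_b$ref_af
  data.frame(chrom = freq_a$chrom, pos = freq_a$pos,
             ref_af_a = freq_a$ref_af, ref_af_b = freq_b$ref_af,
             delta_af = abs(freq_b$ref_af - freq_a$ref_af),
             informative = !mono, stringsAsFactors = FALSE)
}

#' @describeIn delta_af Convenience wrapper: build both cohorts from sample
#'   metadata by generation label.
#' @param vt A `variant_table`.
#' @param meta Sample metadata (`sample_id`, `generation`).
#' @param generations Length-2 vector, cohorts A and B (default `c(1, 10)`).
#' @export
delta_af_cohorts <- function(vt, meta, generations = c(1L, 10L)) {
  ids <- function(g) meta$sample_id[meta$generation == g]
  delta_af(cohort_ref_freq(vt, ids(generations[1])),
           cohort_ref_freq(vt, ids(generations[2])))
}

#' Bin allele-frequency differences in fixed-width bins
#'
#' Bins are `[0, w)`, `[w, 2w)`, ..., with the final bin closed at 1, so a
#' difference of exactly `w` falls in bin 2 and a difference of 1 in the
#' last bin. `w` must divide 1 evenly.
#'
#' @param delta Numeric vector of differences in `[0, 1]`.
#' @param width Bin width (default 0.05, giving 20 bins).
#' @return Integer bin index per value, with bin labels in
#'   `attr(, "labels")`.
#' @export
bin_delta_af <- function(delta, width = 0.05) {
  if (!is.numeric(width) || width <= 0 || width > 1)
    stop("config error: width must lie in (0, 1]", call. = FALSE)
  nb <- 1 / width
  if (abs(nb - round(nb)) > 1e-8)
    stop("config error: width must divide 1 evenly", call. = FALSE)
  nb <- as.integer(round(nb))
  bin <- pmin(nb, floor(delta / width + 1e-9) + 1L)
  labels <- sprintf("[%.2f,%.2f%s", width * (seq_len(nb) - 1), width * seq_len(nb),
                    c(rep(")", nb - 1L), "]"))
  structure(as.integer(bin), labels = labels, n_bins = nb)
}

#' Annotation-category enrichment of binned allele-frequency shifts
#'
#' For every (bin, category) pair computes the log2 fold change
#' `M = log2((n_bin_cat / n_bin) / (n_cat / n_total))` and a 2x2 chi-squared
#' test of \{site in bin\} x \{site in category\} (no continuity correction;
#' Fisher's exact test is substituted when any expected cell is below 5).
#' `M` is reported as missing (not 0) for empty cells.
#'
#' @param bins Integer bin index per site (from [bin_delta_af()]).
#' @param categories Category label per site.
#' @param fisher_fallback Use Fisher's exact test for sparse tables.
#' @return Data frame `bin`, `category`, `n`, `n_bin`, `n_cat`, `M`, `p`,
#'   `test`.
#' @export
category_enrichment <- function(bins, categories, fisher_fallback = TRUE) {
  stopifnot(length(bins) == length(categories))
  n_total <- length(bins)
  nb <- attr(bins, "n_bins")
  if (is.null(nb)) nb <- max(bins)
  cats <- sort(unique(categories))
  out <- expand.grid(bin = seq_len(nb), category = cats,
                     stringsAsFactors = FALSE)
  out$n <- out$n_bin <- out$n_cat <- 0L
  out$M <- out$p <- NA_real_
  out$test <- NA_character_
  tab <- table(factor(bins, levels = seq_len(nb)), categories)
  n_bin <- rowSums(tab)
  n_cat <- colSums(tab)
  for (r in seq_len(nrow(out))) {
    b <- out$bin[r]; cc <- out$category[r]
    n_bc <- tab[b, cc]
    out$n[r] <- n_bc; out$n_bin[r] <- n_bin[b]; out$n_cat[r] <- n_cat[cc]
    if (n_bin[b] == 0L || n_cat[cc] == 0L) next
    if (n_bc > 0L)
      out$M[r] <- log2((n_bc / n_bin[b]) / (n_cat[cc] / n_total))
    m <- matrix(c(n_bc, n_bin[b] - n_bc,
                  n_cat[cc] - n_bc, n_total - n_bin[b] - n_cat[cc] + n_bc),
                nrow = 2L)
    expected <- outer(rowSums(m), colSums(m)) / n_total
    if (fisher_fallback && any(expected < 5)) {
      out$p[r] <- fisher.test(m)$p.value
      out$test[r] <- "fisher"
    } else {
      out$p[r] <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
      out$test[r] <- "chisq"
    }
  }
  out
}
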