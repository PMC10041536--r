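#' Copy-number classes from normalized copy numbers
#'
#' Rounds normalized copy numbers to the nearest half-integer class
#' (midpoints round half-up); everything rounding above 2 is pooled into
#' the multicopy class `">2"`. Class 1 is the diploid-normal state, 0 a
#' homozygous deletion, 0.5 a hemizygous deletion, 1.5/2 heterozygous and
#' homozygous duplications.
#'
#' @param values Numeric vector or matrix of normalized copy numbers
#'   (must be >= 0).
#' @return Character vector/matrix with levels `"0"`, `"0.5"`, `"1"`,
#'   `"1.5"`, `"2"`, `">2"`.
#' @export
classify_copy_number <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("data error: negative copy number", call. = FALSE)
  cls <- floor(values * 2 + 0.5) / 2      # half-up to nearest half-integer
  out <- ifelse(cls > 2, ">2", format(cls, trim = TRUE))
  out[!is.na(out)] <- sub("\\.0$", "", out[!is.na(out)])
  if (is.matrix(values)) out <- matrix(out, nrow = nrow(values),
                                       dimnames = dimnames(values))
  out
}

cn_class_levels <- c("0", "0.5", "1", "1.5", "2", ">2")

#' Silhouette/MAF quality filter for CNV regions
#'
#' Computes the silhouette coefficient of the 1-D copy-number values with
#' the rounded classes as clusters (mean over samples of
#' `(b - a) / max(a, b)`), and the minor-state frequency (combined
#' frequency of all non-modal classes). A CNVR is kept iff silhouette
#' > `min_sil` and minor-state frequency > `min_maf`; single-class CNVRs
#' are dropped as monomorphic.
#'
#' @param values Numeric vector of normalized copy numbers for one CNVR.
#' @param min_sil Silhouette threshold (default 0.7, strict).
#' @param min_maf Minor-state frequency threshold (default 0.05, strict).
#' @return List `keep`, `silhouette`, `minor_freq`, `reason`.
#' @export
silhouette_filter <- function(values, min_sil = 0.7, min_maf = 0.05) {
  cls <- classify_copy_number(values)
  tab <- table(cls)
  if (length(tab) < 2L)
    return(list(keep = FALSE, silhouette = NA_real_, minor_freq = 0,
                reason = "monomorphic"))
  minor_freq <- 1 - max(tab) / length(values)
  sil <- cluster::silhouette(as.integer(factor(cls)), dist(values))
  score <- mean(sil[, "sil_width"])
  keep <- score > min_sil && minor_freq > min_maf
  reason <- if (keep) NA_character_
    else if (minor_freq <= min_maf) "low minor-state frequency"
    else "poor class separation"
  list(keep = keep, silhouette = score, minor_freq = minor_freq,
       reason = reason)
}

#' Relative frequency difference (RFD) between two cohorts
#'
#' Contrast of a CNVR's carrier frequency between cohorts, signed as
#' (query - reference), i.e. last minus first generation. The default
#' `zscore` form divides the difference by its pooled-frequency standard
#' error, `(fB - fA) / sqrt(fbar (1 - fbar) (1/nA + 1/nB))`; `relative`
#' is the bounded form `2 (fB - fA) / (fB + fA)`.
#'
#' @param freq_a,freq_b Carrier frequencies in the reference (first) and
#'   query (last) cohorts.
#' @param n_a,n_b Cohort sizes (required for `zscore`).
#' @param method `"zscore"` or `"relative"`.
#' @return The statistic (vectorized); `NA` where undefined (pooled
#'   frequency 0 or 1 under `zscore`, both frequencies 0 under
#'   `relative`).
#' @export
rfd <- function(freq_a, freq_b, n_a = NULL, n_b = NULL,
                method = c("zscore", "relative")) {
  method <- match.arg(method)
  if (method == "relative") {
    out <- ifelse(freq_a + freq_b > 0,
                  2 * (freq_b - freq_a) / (freq_b + freq_a),
                  ifelse(freq_a == freq_b, 0, NA_real_))
    return(out)
  }
  stopifnot(!is.null(n_a), !is.null(n_b))
  fbar <- (n_a * freq_a + n_b * freq_b) / (n_a + n_b)
  se <- sqrt(fbar * (1 - fbar) * (1 / n_a + 1 / n_b))
  ifelse(fbar <= 0 | fbar >= 1, NA_real_,
         ifelse(freq_a == freq_b, 0, (freq_b - freq_a) / se))
}

#' Carrier frequency per cohort
#'
#' Fraction of samples whose copy-number class differs from the
#' diploid-normal class `"1"`.
#'
#' @param classes Class matrix (CNVR x sample) from
#'   [classify_copy_number()].
#' @param sample_ids Columns forming the cohort.
#' @return Numeric vector, one carrier frequency per CNVR.
#' @export
carrier_frequency <- function(classes, sample_ids) {
  sub <- classes[, sample_ids, drop = FALSE]
  rowMeans(sub != "1")
}

#' Screen CNVRs by empirical top-quantile |RFD|
#'
#' Selects the CNVRs whose |RFD| reaches the `(1 - tail_fraction)`
#' empirical quantile of all finite |RFD| values (ties at the cutoff are
#' kept) and reports the realized cutoff.
#'
#' @param rfd_values RFD per CNVR.
#' @param tail_fraction Upper-tail mass (default 0.05).
#' @return List `selected` (logical per CNVR), `cutoff`.
#' @export
screen_cnvrs <- function(rfd_values, tail_fraction = 0.05) {
  a <- abs(rfd_values)
  if (!length(a) || all(is.na(a))) stop("empty input", call. = FALSE)
  cutoff <- unname(quantile(a, 1 - tail_fraction, type = 7, na.rm = TRUE))
  list(selected = !is.na(a) & a >= cutoff, cutoff = cutoff)
}

#' Phenotypic variance explained by a CNVR
#'
#' R-squared of a least-squares regression of the phenotype on the
#' copy-number class, with the class coded linearly (`">2"` as 2.5) or as
#' an unordered factor (ANOVA coding).
#'
#' @param classes Class vector (one CNVR, one entry per sample).
#' @param phenotype Phenotype vector.
#' @param coding `"linear"` or `"anova"`.
#' @return R-squared, or `NA` when only one class is present.
#' @export
cnv_variance_explained <- function(classes, phenotype,
                                   coding = c("linear", "anova")) {
  coding <- match.arg(coding)
  if (length(unique(classes)) < 2L) return(NA_real_)
  x <- if (coding == "linear") {
    num <- c(`0` = 0, `0.5` = 0.5, `1` = 1, `1.5` = 1.5, `2` = 2, `>2` = 2.5)
    num[classes]
  } else factor(classes)
  summary(lm(phenotype ~ x))$r.squared
}

#' Carrier-frequency trajectory of CNVRs across generations
#'
#' @param classes Class matrix (CNVR x sample).
#' @param meta Sample metadata (`sample_id`, `generation`).
#' @return Data frame `cnvr`, `generation`, `carrier_freq`, `n`.
#' @export
cnv_frequency_trajectory <- function(classes, meta) {
  gens <- sort(unique(meta$generation))
  out <- lapply(gens, function(g) {
    ids <- meta$sample_id[meta$generation == g]
    data.frame(cnvr = rownames(classes) %||% seq_len(nrow(classes)),
               generation = g,
               carrier_freq = carrier_frequency(classes, ids),
               n = length(ids), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full CNV screen between two cohorts
#'
#' Quality-filters CNVRs (silhouette and minor-state frequency), computes
#' carrier frequencies in the two cohorts, the RFD statistic, and applies
#' the empirical top-quantile screen.
#'
#' @param values Normalized copy-number matrix (CNVR x sample).
#' @param meta Sample metadata (`sample_id`, `generation`).
#' @param generations Reference and query generations (default `c(1, 10)`).
#' @param tail_fraction Screen tail (default 0.05).
#' @param method RFD form (see [rfd()]).
#' @param min_sil,min_maf Quality-filter thresholds.
#' @return Data frame per CNVR: `silhouette`, `minor_freq`, `qc_pass`,
#'   `freq_ref`, `freq_query`, `rfd`, `selected`, with the realized cutoff
#'   in `attr(, "cutoff")`.
#' @export
cnv_screen <- function(values, meta, generations = c(1L, 10L),
                       tail_fraction = 0.05, method = "zscore",
                       min_sil = 0.7, min_maf = 0.05) {
  classes <- classify_copy_number(values)
  qc <- lapply(seq_len(nrow(values)), function(i)
    silhouette_filter(values[i, ], min_sil = min_sil, min_maf = min_maf))
  ids_ref <- meta$sample_id[meta$generation == generations[1]]
  ids_q <- meta$sample_id[meta$generation == generations[2]]
  f_ref <- carrier_frequency(classes, ids_ref)
  f_q <- carrier_frequency(classes, ids_q)
  out <- data.frame(
    cnvr = rownames(values) %||% as.character(seq_len(nrow(values))),
    silhouette = vapply(qc, `[[`, 0, "silhouette"),
    minor_freq = vapply(qc, `[[`, 0, "minor_freq"),
    qc_pass = vapply(qc, `[[`, TRUE, "keep"),
    freq_ref = f_ref, freq_query = f_q,
    rfd = rfd(f_ref, f_q, length(ids_ref), length(ids_q), method = method),
    selected = FALSE, stringsAsFactors = FALSE)
  pass <- which(out$qc_pass & !is.na(out$rfd))
  if (length(pass)) {
    scr <- screen_cnvrs(out$rfd[pass], tail_fraction)
    out$selected[pass] <- scr$selected
    attr(out, "cutoff") <- scr$cutoff
  }
  out
}
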