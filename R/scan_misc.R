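#' Empirical tail threshold
#'
#' Returns the `(1 - tail_fraction)` empirical quantile (type-7 linear
#' interpolation) of a statistic; for two-sided statistics both tails are
#' returned. A warning is emitted when fewer than `100 / tail_fraction`
#' values are supplied, since extreme quantiles are then poorly resolved.
#'
#' @param values Numeric vector (NAs dropped).
#' @param tail_fraction Upper-tail mass (default 0.01, the top 1%).
#' @param side `"upper"`, `"lower"` or `"two"`.
#' @return Named numeric: `upper` and/or `lower` cutoffs.
#' @export
empirical_threshold <- function(values, tail_fraction = 0.01,
                                side = c("upper", "lower", "two")) {
  side <- match.arg(side)
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  if (length(values) < 100 / tail_fraction)
    warning(sprintf("only %d values for a %.3g tail; threshold is noisy",
                    length(values), tail_fraction), call. = FALSE)
  up <- unname(quantile(values, 1 - tail_fraction, type = 7))
  lo <- unname(quantile(values, tail_fraction, type = 7))
  switch(side,
         upper = c(upper = up),
         lower = c(lower = lo),
         two = c(lower = lo, upper = up))
}

# Merge a window/region data frame into disjoint intervals per chromosome.
merge_intervals <- function(df) {
  if (!nrow(df)) return(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)))
  out <- lapply(unique(df$chrom), function(ch) {
    s <- df[df$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(start = s$start + 1L, end = s$end))
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate regions from the joint Fst x XP-EHH scan
#'
#' Intersects the union of above-threshold Fst windows with the union of
#' above-threshold XP-EHH windows and merges adjacent or overlapping
#' surviving intervals into candidate regions. An empty intersection is a
#' valid (empty) result.
#'
#' @param fst_above,xpehh_above Window data frames (`chrom`, `start`,
#'   `end`) already restricted to above-threshold windows, in the same
#'   coordinate system (0-based half-open).
#' @return Data frame `chrom`, `start`, `end`, `provenance`.
#' @export
intersect_candidate_windows <- function(fst_above, xpehh_above) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), provenance = character(0))
  if (!nrow(fst_above) || !nrow(xpehh_above)) return(empty)
  out <- lapply(intersect(unique(fst_above$chrom), unique(xpehh_above$chrom)),
    function(ch) {
      f <- fst_above[fst_above$chrom == ch, , drop = FALSE]
      x <- xpehh_above[xpehh_above$chrom == ch, , drop = FALSE]
      ir <- IRanges::intersect(
        IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end)),
        IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end)))
      ir <- IRanges::reduce(ir)
      if (!length(ir)) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), provenance = "fst,xpehh")
    })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Average pairwise difference per base pair: per site the pairwise
#' difference rate among `n` haplotypes is `2 c (n - c) / (n (n - 1))`
#' (`c` = alternate-allele count); window pi sums this over sites and
#' divides by window length. Windows without sites get pi = 0 and
#' `n_snps = 0`.
#'
#' @param hap Haplotype matrix (haplotypes x sites), one cohort.
#' @param sites Site table (`chrom`, 1-based `pos`) matching the columns.
#' @param window,step Window width and step, bp.
#' @param chrom_lengths Named chromosome lengths (default: max position).
#' @return Data frame `chrom`, `start`, `end`, `stat`, `value`, `n_snps`.
#' @export
nucleotide_diversity <- function(hap, sites, window = 10000, step = 5000,
                                 chrom_lengths = NULL) {
  n <- nrow(hap)
  if (n < 2L) stop("need >= 2 haplotypes", call. = FALSE)
  cnt <- colSums(hap)
  persite <- 2 * cnt * (n - cnt) / (n * (n - 1))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
  windows <- make_windows(chrom_lengths, window, step)
  idx <- window_site_index(sites, windows)
  val <- vapply(seq_along(idx), function(w) {
    sum(persite[idx[[w]]]) / (windows$end[w] - windows$start[w])
  }, 0)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             stat = "pi", value = val, n_snps = lengths(idx),
             stringsAsFactors = FALSE)
}

#' Genotype principal component analysis (Patterson normalization)
#'
#' Mean-imputes missing dosages, drops monomorphic sites, centers each site
#' at `2p` and scales by `sqrt(p(1-p))`, then eigendecomposes the sample
#' covariance matrix.
#'
#' @param dosage Dosage matrix, sites x samples.
#' @param k Number of components returned.
#' @return List with `scores` (samples x k orthonormal eigenvectors),
#'   `values` (all eigenvalues) and `varprop` (variance proportions of the
#'   returned components).
#' @export
genotype_pca <- function(dosage, k = 3L) {
  n <- ncol(dosage)
  if (n < k + 1L) stop("need more samples than components", call. = FALSE)
  rm <- rowMeans(dosage, na.rm = TRUE)
  if (anyNA(dosage)) {
    miss <- which(is.na(dosage), arr.ind = TRUE)
    dosage[miss] <- rm[miss[, 1L]]
  }
  p <- rm / 2
  keep <- p > 0 & p < 1
  z <- (dosage[keep, , drop = FALSE] - 2 * p[keep]) / sqrt(p[keep] * (1 - p[keep]))
  m <- sum(keep)
  if (m == 0L) stop("all sites monomorphic", call. = FALSE)
  cv <- crossprod(z) / m
  e <- eigen(cv, symmetric = TRUE)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(dosage)
  list(scores = scores, values = e$values,
       varprop = e$values[seq_len(k)] / sum(pmax(e$values, 0)))
}

#' Allele-frequency trajectories across sampled generations
#'
#' Reference-allele frequency of each requested site in every sampled
#' generation, with the non-missing allele counts that produced it.
#' A generation with zero samples yields a missing entry, not zero.
#'
#' @param vt A [variant_table][new_variant_table].
#' @param meta Sample metadata (`sample_id`, `generation`).
#' @param site_index Site rows to track (default: all).
#' @return Long data frame `index`, `chrom`, `pos`, `generation`,
#'   `ref_af`, `n_alleles`.
#' @export
frequency_trajectory <- function(vt, meta, site_index = NULL) {
  if (is.null(site_index)) site_index <- seq_len(n_sites(vt))
  gens <- sort(unique(meta$generation))
  out <- lapply(gens, function(g) {
    ids <- meta$sample_id[meta$generation == g]
    if (!length(ids))
      return(data.frame(index = site_index,
                        chrom = vt$sites$chrom[site_index],
                        pos = vt$sites$pos[site_index], generation = g,
                        ref_af = NA_real_, n_alleles = 0L))
    fr <- site_frequencies(vt, samples = ids)
    data.frame(index = site_index, chrom = vt$sites$chrom[site_index],
               pos = vt$sites$pos[site_index], generation = g,
               ref_af = fr$ref_af[site_index],
               n_alleles = 2L * fr$n_called[site_index])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nonsynonymous/synonymous count ratio
#'
#' Count ratio (not rate-normalized) of nonsynonymous to synonymous coding
#' SNPs; the effect labels are inputs, not computed here.
#'
#' @param labels Character vector with values `"nonsynonymous"` /
#'   `"synonymous"`.
#' @return List with `n_nonsyn`, `n_syn` and `ratio` (`NA` with a warning
#'   when no synonymous SNPs are present).
#' @export
dnds_proportion <- function(labels) {
  bad <- setdiff(unique(labels), c("nonsynonymous", "synonymous"))
  if (length(bad))
    stop("unknown effect label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_non <- sum(labels == "nonsynonymous")
  n_syn <- sum(labels == "synonymous")
  ratio <- if (n_syn == 0L) {
    warning("no synonymous SNPs; ratio undefined", call. = FALSE)
    NA_real_
  } else n_non / n_syn
  list(n_nonsyn = n_non, n_syn = n_syn, ratio = ratio)
}
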