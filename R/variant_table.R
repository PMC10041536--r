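#' Variant table container
#'
#' Internal substrate of every statistic in the package: a site table
#' (`chrom`, `pos` 1-based, `ref`, `alt`, optional `mean_depth`), a dosage
#' matrix (`n_sites x n_samples`, values 0/1/2 or `NA` for missing) and,
#' when phased, a haplotype matrix (`n_sites x 2*n_samples`, columns
#' `2i-1`/`2i` holding the two haplotypes of sample `i`).
#'
#' @param sites Site data frame.
#' @param dosage Integer matrix, sites x samples.
#' @param haplotypes Optional 0/1 matrix, sites x 2*samples.
#' @param samples Character vector of sample ids (defaults to dosage
#'   colnames).
#' @param phased Logical; must be `TRUE` when `haplotypes` is supplied.
#' @return An object of class `variant_table`.
#' @export
new_variant_table <- function(sites, dosage, haplotypes = NULL,
                              samples = colnames(dosage), phased = !is.null(haplotypes)) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(dosage))
  if (!is.null(haplotypes)) {
    stopifnot(nrow(haplotypes) == nrow(sites),
              ncol(haplotypes) == 2L * ncol(dosage))
    odd <- 2L * seq_len(ncol(dosage)) - 1L
    hsum <- haplotypes[, odd, drop = FALSE] +
      haplotypes[, odd + 1L, drop = FALSE]
    ok <- is.na(dosage) | hsum == dosage
    if (!all(ok, na.rm = TRUE))
      stop("variant_table: dosage must equal the haplotype sum", call. = FALSE)
  }
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(dosage)))
  # positions must be strictly increasing within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("variant_table: positions must be strictly increasing within '",
           ch, "'", call. = FALSE)
  }
  structure(list(sites = sites, dosage = dosage, haplotypes = haplotypes,
                 samples = samples, phased = isTRUE(phased)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$dosage),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt A `variant_table`.
#' @return Integer count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) ncol(vt$dosage)

#' Subset a variant table
#'
#' @param vt A `variant_table`.
#' @param sites Integer/logical index over sites (optional).
#' @param samples Integer/logical/character index over samples (optional).
#' @return A `variant_table`.
#' @export
subset_variant_table <- function(vt, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(vt))
  if (is.null(samples)) samples <- seq_len(n_samples(vt))
  if (is.character(samples)) samples <- match(samples, vt$samples)
  if (anyNA(samples)) stop("unknown sample id", call. = FALSE)
  if (is.logical(samples)) samples <- which(samples)
  hap <- NULL
  if (!is.null(vt$haplotypes)) {
    hcols <- as.vector(rbind(2L * samples - 1L, 2L * samples))
    hap <- vt$haplotypes[sites, hcols, drop = FALSE]
  }
  new_variant_table(vt$sites[sites, , drop = FALSE],
                    vt$dosage[sites, samples, drop = FALSE],
                    haplotypes = hap,
                    samples = vt$samples[samples], phased = vt$phased)
}

#' Per-site allele frequencies and missingness
#'
#' Frequencies are computed on non-missing alleles only.
#'
#' @param vt A `variant_table`.
#' @param samples Optional sample subset (ids or indices).
#' @return Data frame with `alt_af`, `ref_af`, `maf`, `max_af`,
#'   `missing_rate`, `n_called` (non-missing diploid genotypes).
#' @export
site_frequencies <- function(vt, samples = NULL) {
  d <- vt$dosage
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, vt$samples)
    d <- d[, samples, drop = FALSE]
  }
  n_called <- rowSums(!is.na(d))
  alt_af <- ifelse(n_called > 0, rowSums(d, na.rm = TRUE) / (2 * n_called), NA_real_)
  ref_af <- 1 - alt_af
  data.frame(alt_af = alt_af, ref_af = ref_af,
             maf = pmin(alt_af, ref_af),
             max_af = pmax(alt_af, ref_af),
             missing_rate = 1 - n_called / ncol(d),
             n_called = n_called)
}
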