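#' Weir-Cockerham (1984) per-site Fst variance components
#'
#' Two-population variance-components estimator computed from sample sizes,
#' allele frequencies and observed heterozygosities. Returns the
#' between-population component `a` and the total `a + b + c`; the site
#' estimate is their ratio (small negative values are a property of the
#' estimator). Sites monomorphic across both cohorts get components (0, 0)
#' and are flagged uninformative.
#'
#' @param dos_a,dos_b Dosage matrices (sites x samples, values 0/1/2 or
#'   `NA`) for the two cohorts over the same sites; vectors are treated as
#'   a single site.
#' @return Data frame with `a`, `d` (= a+b+c), `fst`, `informative`.
#' @export
wc_fst_site <- function(dos_a, dos_b) {
  if (is.null(dim(dos_a))) dos_a <- matrix(dos_a, nrow = 1L)
  if (is.null(dim(dos_b))) dos_b <- matrix(dos_b, nrow = 1L)
  stopifnot(nrow(dos_a) == nrow(dos_b))
  n1 <- rowSums(!is.na(dos_a)); n2 <- rowSums(!is.na(dos_b))
  if (any(n1 < 1L) || any(n2 < 1L))
    stop("each cohort needs >= 1 non-missing genotype per site", call. = FALSE)
  p1 <- rowSums(dos_a, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dos_b, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(dos_a == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(dos_b == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / 2
  nC <- r * nbar - (n1^2 + n2^2) / (r * nbar)          # r - 1 = 1
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nC *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  d <- a + b + cc

  mono <- pbar %in% c(0, 1) & hbar == 0
  a[mono] <- 0; d[mono] <- 0
  informative <- !mono & abs(d) > 1e-12
  data.frame(a = a, d = d,
             fst = ifelse(informative, a / d, NA_real_),
             informative = informative)
}

#' Sliding windows along chromosomes
#'
#' Windows start at 0 and advance by `step`; every window has width
#' `window` except that a chromosome shorter than one window yields a
#' single window covering it. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window,step Window width and step, bp.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window = 10000, step = 5000) {
  if (step > window)
    stop("config error: step > window would leave coverage gaps", call. = FALSE)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= window) return(data.frame(chrom = ch, start = 0, end = len))
    starts <- seq(0, len - window, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window)
  })
  do.call(rbind, out)
}

# Accumulate per-site values into sliding windows. Returns, for each window
# row, the indices of sites whose 0-based position falls in [start, end).
window_site_index <- function(sites, windows) {
  idx <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    pos0 <- sites$pos[si] - 1L
    for (w in wi) {
      sel <- pos0 >= windows$start[w] & pos0 < windows$end[w]
      idx[[w]] <- si[sel]
    }
  }
  idx
}

#' Windowed Fst (ratio of sums)
#'
#' Aggregates per-site Weir-Cockerham components into sliding windows as
#' `sum(a) / sum(a + b + c)` over the informative sites in each window (the
#' ratio-of-sums estimator); windows containing no informative site are
#' omitted.
#'
#' @param sites Site table (`chrom`, 1-based `pos`), sorted by position
#'   within chromosome.
#' @param components Output of [wc_fst_site()] for those sites.
#' @param window,step Window width and step in bp.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   largest site position per chromosome.
#' @param mean_of_sites If `TRUE`, average per-site Fst instead of the
#'   ratio of sums.
#' @return Data frame `chrom`, `start`, `end`, `stat`, `value`, `n_snps`.
#' @export
fst_windows <- function(sites, components, window = 10000, step = 5000,
                        chrom_lengths = NULL, mean_of_sites = FALSE) {
  stopifnot(nrow(sites) == nrow(components))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
  windows <- make_windows(chrom_lengths, window, step)
  idx <- window_site_index(sites, windows)
  val <- vapply(idx, function(ii) {
    ii <- ii[components$informative[ii]]
    if (!length(ii)) return(NA_real_)
    if (mean_of_sites) mean(components$fst[ii])
    else sum(components$a[ii]) / sum(components$d[ii])
  }, 0)
  n <- vapply(idx, function(ii) sum(components$informative[ii]), 0L)
  keep <- n > 0L
  data.frame(chrom = windows$chrom[keep], start = windows$start[keep],
             end = windows$end[keep], stat = "fst", value = val[keep],
             n_snps = n[keep], stringsAsFactors = FALSE)
}
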