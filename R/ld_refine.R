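#' Pairwise linkage disequilibrium r-squared
#'
#' `composite` (default): squared Pearson correlation of genotype dosage
#' vectors, the standard genotype-based estimator for unphased data.
#' `haplotype_em`: `D^2 / (pA pB (1-pA) (1-pB))` from two-locus haplotype
#' frequencies estimated by expectation-maximization on unphased
#' genotypes. Both require both SNPs polymorphic among the non-missing
#' samples; otherwise the value is undefined (`NA`).
#'
#' @param dos_a,dos_b Dosage vectors (0/1/2, `NA` allowed) over the same
#'   samples.
#' @param method `"composite"` or `"haplotype_em"`.
#' @param max_iter,tol EM controls.
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
r2_pair <- function(dos_a, dos_b, method = c("composite", "haplotype_em"),
                    max_iter = 100L, tol = 1e-10) {
  method <- match.arg(method)
  ok <- !is.na(dos_a) & !is.na(dos_b)
  a <- dos_a[ok]; b <- dos_b[ok]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NA_real_)
  if (method == "composite") return(unname(cor(a, b)^2))

  pA <- 1 - mean(a) / 2                 # frequency of allele "0" at locus A
  pB <- 1 - mean(b) / 2
  pAB <- pA * pB                        # start at linkage equilibrium
  n <- length(a)
  for (it in seq_len(max_iter)) {
    # expected count of 0-0 haplotypes; only double heterozygotes are
    # ambiguous between phases (0-0/1-1) and (0-1/1-0)
    nA0 <- 2 - a; nB0 <- 2 - b          # copies of allele 0 per sample
    cnt <- numeric(n)
    dh <- a == 1 & b == 1
    cnt[!dh] <- (nA0 * nB0 / 2)[!dh]    # phase determined when not double-het
    pab <- (1 - pA) - (pB - pAB)        # p(1-1) haplotype
    p_cis <- pAB * pab
    p_trans <- (pA - pAB) * (pB - pAB)
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    cnt[dh] <- w                        # one 0-0 haplotype iff cis phase
    new_pAB <- sum(cnt) / (2 * n)
    if (abs(new_pAB - pAB) < tol) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  D <- pAB - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' r-squared from phased haplotypes
#'
#' Direct haplotype-frequency computation of `D^2 / (pA pB (1-pA)(1-pB))`
#' for two phased 0/1 haplotype vectors (one entry per haplotype).
#'
#' @param hap_a,hap_b 0/1 vectors over the same haplotypes.
#' @return r-squared, or `NA` when either locus is monomorphic.
#' @export
r2_haplotype <- function(hap_a, hap_b) {
  pA <- mean(hap_a == 0)
  pB <- mean(hap_b == 0)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(hap_a == 0 & hap_b == 0)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' r-squared of every SNP in a region against the lead SNP
#'
#' @param dosage Dosage matrix (sites x samples) restricted to the region.
#' @param lead Row index of the lead SNP.
#' @inheritParams r2_pair
#' @return Numeric vector of r-squared values (lead vs itself = 1).
#' @export
r2_to_lead <- function(dosage, lead, method = c("composite", "haplotype_em")) {
  method <- match.arg(method)
  vapply(seq_len(nrow(dosage)), function(i)
    r2_pair(dosage[lead, ], dosage[i, ], method = method), 0)
}

#' Lead SNP of a region
#'
#' The SNP with the largest score (e.g. -log10 p or |window statistic|);
#' ties are broken by the smaller coordinate.
#'
#' @param pos Positions of the scored SNPs in the region.
#' @param score Scores (larger = more extreme).
#' @return Index (into `pos`) of the lead SNP.
#' @export
lead_snp <- function(pos, score) {
  if (!length(pos)) stop("empty region: no scored SNP", call. = FALSE)
  best <- which(score == max(score, na.rm = TRUE))
  best[which.min(pos[best])]
}

#' LD-based refinement of a candidate region
#'
#' The refined region is the `[min, max]` positional envelope of the SNPs
#' whose r-squared with the lead SNP exceeds the threshold, always
#' including the lead itself; when no SNP qualifies the result degenerates
#' to the lead position (flagged).
#'
#' @param pos SNP positions within the region (1-based).
#' @param r2 r-squared of each SNP with the lead (same order).
#' @param lead Index of the lead SNP in `pos`.
#' @param r2_threshold Qualification threshold (default 0.4, strict `>`).
#' @return List `start`, `end` (0-based half-open envelope), `n_snps`
#'   (qualifying count incl. lead), `degenerate`.
#' @export
refine_region <- function(pos, r2, lead, r2_threshold = 0.4) {
  qual <- which(!is.na(r2) & r2 > r2_threshold)
  qual <- union(qual, lead)
  degenerate <- length(qual) == 1L
  p <- pos[qual]
  list(start = min(p) - 1L, end = max(p), n_snps = length(qual),
       degenerate = degenerate)
}

#' Total genomic span of a set of regions
#'
#' Sums `end - start` over non-overlapping regions; overlapping input is
#' merged first with a warning.
#'
#' @param regions Data frame `chrom`, `start`, `end` (0-based half-open).
#' @return Total span in bp.
#' @export
region_span <- function(regions) {
  if (!nrow(regions)) return(0)
  merged <- merge_intervals(regions)
  if (nrow(merged) != nrow(regions) ||
      sum(merged$end - merged$start) != sum(regions$end - regions$start))
    warning("overlapping regions merged before measuring span", call. = FALSE)
  sum(merged$end - merged$start)
}

#' Noncoding fraction of a set of annotated SNPs
#'
#' Every category except `exon` counts as noncoding (UTRs included,
#' reflecting their regulatory role).
#'
#' @param categories Annotation category per SNP.
#' @return List `n_noncoding`, `n_total`, `fraction`, `percent`.
#' @export
noncoding_fraction <- function(categories) {
  n <- length(categories)
  if (!n) {
    warning("no SNPs; noncoding fraction undefined", call. = FALSE)
    return(list(n_noncoding = 0L, n_total = 0L, fraction = NA_real_,
                percent = NA_real_))
  }
  nn <- sum(categories != "exon")
  list(n_noncoding = nn, n_total = n, fraction = nn / n,
       percent = 100 * nn / n)
}
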