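#' Extended haplotype homozygosity around a core site
#'
#' EHH at flanking position `x` is the probability that two random carrier
#' haplotypes are identical at every site from the core out to `x`:
#' `sum_g C(e_g, 2) / C(n_c, 2)` over the groups of identical extended
#' haplotypes. The curve equals 1 at the core and is non-increasing with
#' distance; computation stops once it falls below `cutoff` (or at the
#' chromosome end).
#'
#' @param hap Phased haplotype matrix, haplotypes x sites, for one
#'   chromosome; `NA` values are rejected (phase required).
#' @param positions 1-based bp positions of the sites (increasing).
#' @param core Core site index (column of `hap`).
#' @param core_allele Core allele (0 or 1) whose carriers are followed;
#'   `NULL` follows every haplotype (the combined curve used by XP-EHH).
#' @param cutoff Decay cutoff (default 0.05).
#' @return Data frame `side` ("left"/"right"/"core"), `index`, `pos`,
#'   `ehh`, ordered by position. When a single core allele is followed the
#'   core EHH is 1; for the combined curve it is the core-site haplotype
#'   homozygosity, since haplotype identity includes the core allele.
#'   Values below `cutoff` are kept (one per side at most) so callers can
#'   see where the curve was truncated.
#' @export
ehh <- function(hap, positions, core, core_allele = NULL, cutoff = 0.05) {
  if (anyNA(hap))
    stop("phase required: haplotype matrix contains missing values",
         call. = FALSE)
  carriers <- if (is.null(core_allele)) seq_len(nrow(hap)) else
    which(hap[, core] == core_allele)
  nc <- length(carriers)
  if (nc < 2L)
    stop("need >= 2 carriers of the core allele", call. = FALSE)
  core_ehh <- if (is.null(core_allele)) {
    cnt <- table(hap[carriers, core])
    sum(choose(cnt, 2)) / choose(nc, 2)
  } else 1
  right <- ehh_side_cpp(hap, core - 1L, carriers - 1L, cutoff, 1L)
  left <- ehh_side_cpp(hap, core - 1L, carriers - 1L, cutoff, -1L)
  ir <- core + seq_along(right)
  il <- rev(core - seq_along(left))
  out <- rbind(
    data.frame(side = rep("left", length(il)), index = il,
               pos = positions[il], ehh = rev(left)),
    data.frame(side = "core", index = core, pos = positions[core],
               ehh = core_ehh),
    data.frame(side = rep("right", length(ir)), index = ir,
               pos = positions[ir], ehh = right)
  )
  rownames(out) <- NULL
  out
}

# Integrated EHH: trapezoidal integral of the curve over bp, both sides,
# truncated at the last point still >= cutoff.
ihh_from_curve <- function(curve, cutoff = 0.05) {
  int_side <- function(side_df, core_row) {
    keep <- side_df[side_df$ehh >= cutoff, , drop = FALSE]
    if (!nrow(keep)) return(0)
    xs <- c(core_row$pos, keep$pos)
    ys <- c(core_row$ehh, keep$ehh)
    ord <- order(xs)
    abs(pracma::trapz(xs[ord], ys[ord]))
  }
  core_row <- curve[curve$side == "core", , drop = FALSE]
  int_side(curve[curve$side == "right", , drop = FALSE], core_row) +
    int_side(curve[curve$side == "left", , drop = FALSE], core_row)
}

#' Integrated EHH (iHH) of the combined curve at a core site
#'
#' @inheritParams ehh
#' @return iHH in bp units.
#' @export
ihh <- function(hap, positions, core, cutoff = 0.05) {
  ihh_from_curve(ehh(hap, positions, core, core_allele = NULL,
                     cutoff = cutoff), cutoff)
}

#' Cross-population EHH (XP-EHH) per core site
#'
#' For each core site, integrates the combined-allele EHH curve over
#' physical distance in the reference and query cohorts separately and
#' takes `ln(iHH_query / iHH_ref)`; in the emulated design the first
#' generation is the reference and the last the query, so positive values
#' mark haplotypes unusually long in the later generation. Values are
#' standardized to mean 0, sd 1 over all scored sites by [xpehh_scan()].
#' Sites where either integral is zero are skipped (value `NA`, reason
#' recorded).
#'
#' @param hap_ref,hap_query Phased haplotype matrices (haplotypes x sites)
#'   on the same site set (one chromosome).
#' @param positions 1-based positions.
#' @param cores Core site indices (default: sites polymorphic in the union
#'   of both cohorts).
#' @param cutoff EHH decay cutoff.
#' @return Data frame `index`, `pos`, `ihh_ref`, `ihh_query`, `xpehh`
#'   (unstandardized), `skipped`.
#' @export
xpehh <- function(hap_ref, hap_query, positions, cores = NULL, cutoff = 0.05) {
  stopifnot(ncol(hap_ref) == ncol(hap_query))
  if (is.null(cores)) {
    counts <- colSums(hap_ref) + colSums(hap_query)
    cores <- which(counts > 0 & counts < nrow(hap_ref) + nrow(hap_query))
  }
  out <- data.frame(index = cores, pos = positions[cores],
                    ihh_ref = NA_real_, ihh_query = NA_real_,
                    xpehh = NA_real_, skipped = FALSE)
  for (k in seq_along(cores)) {
    i <- cores[k]
    ir <- ihh(hap_ref, positions, i, cutoff)
    iq <- ihh(hap_query, positions, i, cutoff)
    out$ihh_ref[k] <- ir
    out$ihh_query[k] <- iq
    if (ir <= 0 || iq <= 0) out$skipped[k] <- TRUE
    else out$xpehh[k] <- log(iq / ir)
  }
  out
}

#' Genome-wide XP-EHH scan with genome-wide standardization
#'
#' Runs [xpehh()] chromosome by chromosome on two cohorts of a phased
#' [variant_table][new_variant_table] and standardizes the pooled
#' unstandardized values to mean 0, sd 1.
#'
#' @param vt A phased `variant_table`.
#' @param ref_ids,query_ids Sample ids of the reference and query cohorts.
#' @param cutoff EHH decay cutoff.
#' @return Data frame `chrom`, `pos`, `index` (site row in `vt`),
#'   `xpehh`, `xpehh_std`, `skipped`.
#' @export
xpehh_scan <- function(vt, ref_ids, query_ids, cutoff = 0.05) {
  if (!vt$phased || is.null(vt$haplotypes))
    stop("phase required: XP-EHH needs phased haplotypes", call. = FALSE)
  hap_cols <- function(ids) {
    j <- match(ids, vt$samples)
    if (anyNA(j)) stop("unknown sample id in cohort", call. = FALSE)
    as.vector(rbind(2L * j - 1L, 2L * j))
  }
  rc <- hap_cols(ref_ids); qc <- hap_cols(query_ids)
  res <- list()
  for (ch in unique(vt$sites$chrom)) {
    si <- which(vt$sites$chrom == ch)
    hr <- t(vt$haplotypes[si, rc, drop = FALSE])
    hq <- t(vt$haplotypes[si, qc, drop = FALSE])
    x <- xpehh(hr, hq, vt$sites$pos[si], cutoff = cutoff)
    x$chrom <- ch
    x$index <- si[x$index]
    res[[ch]] <- x
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  mu <- mean(res$xpehh, na.rm = TRUE)
  sdv <- sd(res$xpehh, na.rm = TRUE)
  res$xpehh_std <- if (isTRUE(sdv > 0)) (res$xpehh - mu) / sdv else NA_real_
  res[, c("chrom", "pos", "index", "ihh_ref", "ihh_query", "xpehh",
          "xpehh_std", "skipped")]
}

#' Window aggregation of per-site XP-EHH
#'
#' The window score is the mean standardized XP-EHH over the scored sites
#' in the window (`agg = "mean"`, the default: averaging suppresses
#' single-site noise in the integrals) or the value of the site with the
#' largest absolute standardized value (`agg = "max"`); windows with no
#' scored site are omitted.
#'
#' @param scan Output of [xpehh_scan()].
#' @param window,step Window width and step in bp.
#' @param chrom_lengths Named chromosome lengths (default: max scored
#'   position per chromosome).
#' @param agg `"mean"` or `"max"`.
#' @return Data frame `chrom`, `start`, `end`, `stat`, `value`, `n_snps`.
#' @export
xpehh_windows <- function(scan, window = 10000, step = 5000,
                          chrom_lengths = NULL, agg = c("mean", "max")) {
  agg <- match.arg(agg)
  scored <- scan[!is.na(scan$xpehh_std), , drop = FALSE]
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(scored$pos, scored$chrom, max)
  windows <- make_windows(chrom_lengths, window, step)
  idx <- window_site_index(scored, windows)
  val <- vapply(idx, function(ii) {
    if (!length(ii)) return(NA_real_)
    v <- scored$xpehh_std[ii]
    if (agg == "mean") mean(v) else v[which.max(abs(v))]
  }, 0)
  n <- lengths(idx)
  keep <- n > 0L
  data.frame(chrom = windows$chrom[keep], start = windows$start[keep],
             end = windows$end[keep], stat = "xpehh", value = val[keep],
             n_snps = n[keep], stringsAsFactors = FALSE)
}
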