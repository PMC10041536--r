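#' Normalize an annotation track
#'
#' Merges overlapping or adjacent intervals of the same category (silently)
#' and errors when intervals of different categories overlap, since every
#' site must receive exactly one category. Coordinates are 0-based
#' half-open.
#'
#' @param track Data frame `chrom`, `start`, `end`, `category`.
#' @return Normalized track (same columns, sorted).
#' @export
normalize_annotation <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "category") %in% names(track)))
  if (any(track$end <= track$start))
    stop("annotation error: intervals must satisfy end > start", call. = FALSE)
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    pieces <- lapply(split(sub, sub$category), function(s) {
      r <- IRanges::reduce(IRanges::IRanges(start = s$start + 1L, end = s$end))
      data.frame(chrom = ch, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), category = s$category[1],
                 stringsAsFactors = FALSE)
    })
    merged <- do.call(rbind, pieces)
    ir <- IRanges::IRanges(start = merged$start + 1L, end = merged$end)
    hits <- IRanges::findOverlaps(ir, ir)
    off_diag <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
    if (any(off_diag)) {
      i <- S4Vectors::queryHits(hits)[off_diag][1]
      j <- S4Vectors::subjectHits(hits)[off_diag][1]
      stop(sprintf(
        "annotation ambiguity: %s [%d,%d) '%s' overlaps [%d,%d) '%s'",
        ch, merged$start[i], merged$end[i], merged$category[i],
        merged$start[j], merged$end[j], merged$category[j]), call. = FALSE)
    }
    out[[ch]] <- merged[order(merged$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign an annotation category to each site
#'
#' A 1-based site position `p` falls in a 0-based half-open interval
#' `[start, end)` iff `start <= p - 1 < end`. Sites outside every interval
#' are `intergenic`.
#'
#' @param sites Data frame with `chrom` and 1-based `pos`.
#' @param track Annotation track (`chrom`, `start`, `end`, `category`,
#'   0-based half-open); normalized internally via
#'   [normalize_annotation()].
#' @return Character vector of categories, one per site.
#' @export
intersect_with_annotation <- function(sites, track) {
  track <- normalize_annotation(track)
  out <- rep("intergenic", nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    sub <- track[track$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    q <- IRanges::IRanges(start = sites$pos[si], end = sites$pos[si])
    s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(q, s, select = "first")
    hit <- !is.na(hits)
    out[si[hit]] <- sub$category[hits[hit]]
  }
  out
}
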