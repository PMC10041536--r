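#' Write a variant table to VCF v4.2
#'
#' Phased tables are written with `|`-separated genotypes, unphased ones
#' with `/`. Per-site mean depth, when present in the site table, is stored
#' in the INFO field `MDP`. Paths ending in `.gz` are gzip-compressed.
#'
#' @param vt A [variant_table][new_variant_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tempsel",
    sprintf("##contig=<ID=%s>", unique(vt$sites$chrom)),
    if (!is.null(vt$sites$mean_depth))
      "##INFO=<ID=MDP,Number=1,Type=Float,Description=\"Mean per-sample depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  writeLines(header, con)

  n <- n_samples(vt)
  m <- n_sites(vt)
  if (vt$phased) {
    a <- vt$haplotypes[, seq(1L, 2L * n, 2L), drop = FALSE]
    b <- vt$haplotypes[, seq(2L, 2L * n, 2L), drop = FALSE]
    gt <- matrix(paste0(a, "|", b), nrow = m)
    gt[is.na(a) | is.na(b)] <- ".|."
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[vt$dosage + 1L], nrow = m)
    gt[is.na(vt$dosage)] <- "./."
  }
  info <- if (!is.null(vt$sites$mean_depth))
    sprintf("MDP=%.4g", vt$sites$mean_depth) else rep(".", m)
  lines <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                 vt$sites$alt, ".", "PASS", info, "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (m == 0L) lines <- character(0)
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses GT fields (`./.` becomes missing, not zero) and preserves phase:
#' the haplotype matrix is kept only when every non-missing genotype is
#' phased. Multi-allelic records are rejected (naming the first offending
#' site) or dropped, per `multiallelic`.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param multiallelic `"error"` (default, strict mode) or `"drop"`.
#' @return List with `genotypes` (a `variant_table`) and `meta` (a sample
#'   metadata stub with `sample_id`).
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic record at ", fix$CHROM[multi][1], ":",
           fix$POS[multi][1], " (strict mode)", call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  haploid_or_missing <- is.na(gt) | a1 == "." | a2 == "." | sep == ""
  a1[haploid_or_missing] <- NA
  a2[haploid_or_missing] <- NA
  h1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  h2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  dosage <- h1 + h2
  colnames(dosage) <- samples
  phased <- all(sep[!haploid_or_missing] == "|") && any(!haploid_or_missing)

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  mdp <- suppressWarnings(vcfR::extract.info(v, "MDP", as.numeric = TRUE))
  if (!is.null(mdp) && any(!is.na(mdp))) sites$mean_depth <- mdp

  hap <- NULL
  if (phased) {
    hap <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
    hap[, seq(1L, 2L * ncol(gt), 2L)] <- h1
    hap[, seq(2L, 2L * ncol(gt), 2L)] <- h2
  }
  vt <- new_variant_table(sites, dosage, haplotypes = hap, samples = samples,
                          phased = phased)
  list(genotypes = vt, meta = data.frame(sample_id = samples,
                                         stringsAsFactors = FALSE))
}

#' Read/write tab-separated tables (metadata, phenotypes, windows)
#'
#' Thin wrappers fixing the dialect used across the package: header line,
#' tabs, no quoting, no row names.
#'
#' @param x Data frame to write.
#' @param path File path (`.gz` supported on read and write).
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else path
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read/write BED3+category annotation tracks
#'
#' BED coordinates are 0-based half-open on disk and are kept 0-based
#' half-open internally; the category lives in BED column 4.
#'
#' @param track Data frame `chrom`, `start`, `end`, `category`.
#' @param path File path.
#' @return `read_bed()` returns the track data frame.
#' @export
write_bed <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  data.frame(chrom = as.character(gr$seqnames),
             start = gr$start - 1L,   # back to 0-based half-open
             end = gr$end,
             category = gr$name, stringsAsFactors = FALSE)
}
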