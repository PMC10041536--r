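#' Variant filtering profiles
#'
#' Applies one of the two site-filter profiles used in the emulated study:
#'
#' * `discovery` keeps biallelic sites with mean per-sample depth strictly
#'   between 3x and 30x, minor allele frequency > 0.05, major (most common)
#'   allele frequency < 0.99 and missing rate < 0.1;
#' * `afd` (the allele-frequency-difference set) keeps sites with missing
#'   rate <= 0.1, MAF > 0.01 and 5x <= mean depth <= 30x.
#'
#' All boundaries are strict or inclusive exactly as listed (a MAF of 0.05
#' is removed under `discovery`). Frequencies are computed on non-missing
#' alleles only. When the table carries no depth annotation (simulated
#' data), depth criteria are skipped with a warning. Each rejected site is
#' attributed to its first failing criterion in the order
#' depth, maxaf, maf, missing; max-AF is tested before MAF because for a
#' biallelic site a failing major-allele frequency implies a failing MAF.
#' Filtering is idempotent.
#'
#' @param vt A [variant_table][new_variant_table].
#' @param profile `"discovery"` or `"afd"`.
#' @return List with `table` (the filtered `variant_table`), `rejections`
#'   (named integer vector: depth, maxaf, maf, missing), `n_input`,
#'   `n_kept`.
#' @export
filter_variants <- function(vt, profile = c("discovery", "afd")) {
  profile <- tryCatch(match.arg(profile),
                      error = function(e) stop("config error: unknown filter profile",
                                               call. = FALSE))
  fr <- site_frequencies(vt)
  md <- vt$sites$mean_depth
  have_depth <- !is.null(md) && any(!is.na(md))
  if (!have_depth) {
    warning("no depth annotation; depth criteria skipped", call. = FALSE)
    md <- rep(NA_real_, n_sites(vt))
  }

  if (profile == "discovery") {
    fail_depth <- have_depth & !(md > 3 & md < 30)
    fail_maxaf <- fr$max_af >= 0.99
    fail_maf <- fr$maf <= 0.05
    fail_missing <- fr$missing_rate >= 0.1
  } else {
    fail_depth <- have_depth & !(md >= 5 & md <= 30)
    fail_maxaf <- rep(FALSE, n_sites(vt))
    fail_maf <- fr$maf <= 0.01
    fail_missing <- fr$missing_rate > 0.1
  }
  fail_depth[is.na(fail_depth)] <- FALSE
  # sites where every genotype is missing fail the missingness criterion
  allmiss <- is.na(fr$maf)
  fail_maxaf[allmiss] <- FALSE
  fail_maf[allmiss] <- FALSE
  fail_missing[allmiss] <- TRUE

  first_fail <- rep(NA_character_, n_sites(vt))
  for (crit in c("missing", "maf", "maxaf", "depth")) {  # reverse priority
    f <- switch(crit, depth = fail_depth, maxaf = fail_maxaf,
                maf = fail_maf, missing = fail_missing)
    first_fail[f] <- crit
  }
  keep <- is.na(first_fail)
  rejections <- vapply(c("depth", "maxaf", "maf", "missing"),
                       function(cr) sum(first_fail == cr, na.rm = TRUE), 0L)
  list(table = subset_variant_table(vt, sites = keep),
       rejections = rejections,
       n_input = n_sites(vt), n_kept = sum(keep))
}
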