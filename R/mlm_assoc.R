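#' Kinship matrix from genotype dosages
#'
#' `centered` (default, VanRaden-style): missing dosages are mean-imputed
#' per site, each site is centered, `K = Z'Z / m`, and `K` is rescaled so
#' its mean diagonal equals 1. `ibs`: mean proportion of shared alleles,
#' `1 - mean(|d_i - d_j|) / 2`.
#'
#' @param dosage Dosage matrix, sites x samples.
#' @param method `"centered"` or `"ibs"`.
#' @return Symmetric positive semi-definite `n x n` matrix.
#' @export
kinship_matrix <- function(dosage, method = c("centered", "ibs")) {
  method <- match.arg(method)
  rm <- rowMeans(dosage, na.rm = TRUE)
  if (anyNA(dosage)) {
    miss <- which(is.na(dosage), arr.ind = TRUE)
    dosage[miss] <- rm[miss[, 1L]]
  }
  poly <- rm > 0 & rm < 2
  if (!any(poly)) stop("degenerate kinship: all sites monomorphic",
                       call. = FALSE)
  if (method == "centered") {
    z <- dosage[poly, , drop = FALSE] - rm[poly]
    k <- crossprod(z) / sum(poly)
    k <- k / mean(diag(k))
  } else {
    d <- as.matrix(dist(t(dosage[poly, , drop = FALSE]), method = "manhattan"))
    k <- 1 - d / (2 * sum(poly))
  }
  dimnames(k) <- list(colnames(dosage), colnames(dosage))
  k
}

#' Restricted maximum likelihood for the null mixed model
#'
#' Fits `y = Xb + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by spectral REML: the restricted likelihood is
#' profiled down to the single ratio `delta = sigma_e^2 / sigma_g^2` using
#' the eigendecomposition of the projected kinship `S K S`
#' (`S = I - X(X'X)^-1 X'`), scanned on a log-spaced grid and refined with
#' bounded 1-D optimization.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effect design matrix (including the intercept).
#' @param K Kinship matrix.
#' @return List with `sigma_g2`, `sigma_e2`, `delta`, `h2`
#'   (`sigma_g2 / (sigma_g2 + sigma_e2)`), `loglik` (restricted).
#' @export
reml_null <- function(y, X, K) {
  n <- length(y)
  X <- as.matrix(X)
  q <- qr(X)$rank
  stopifnot(nrow(X) == n, nrow(K) == n, n > q + 1)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- es$values[seq_len(n - q)]
  xi[xi < 0] <- 0
  U <- es$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.vector(crossprod(U, y))^2

  df <- n - q
  rll <- function(log_delta) {
    delta <- exp(log_delta)
    ss <- sum(eta2 / (xi + delta))
    0.5 * (df * (log(df / (2 * pi)) - 1 - log(ss)) - sum(log(xi + delta)))
  }
  grid <- log(10^seq(-5, 5, length.out = 41))
  vals <- vapply(grid, rll, 0)
  if (!any(is.finite(vals)))
    stop("optimization error: restricted likelihood non-finite everywhere",
         call. = FALSE)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(eta2 / (xi + delta)) / df
  sigma_e2 <- delta * sigma_g2
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
       h2 = sigma_g2 / (sigma_g2 + sigma_e2), loglik = opt$objective)
}

#' Mixed-model association scan with fixed variance components
#'
#' Per-SNP generalized least squares under the covariance
#' `sigma_g^2 K + sigma_e^2 I`, with the variance components estimated once
#' on the null model and held fixed (the EMMAX approximation): the spectral
#' transform of `K` whitens the model, after which each SNP is an ordinary
#' regression of the rotated phenotype on the rotated `[X, snp]`. p-values
#' use the t distribution with `n - rank([X, snp])` degrees of freedom.
#' Missing dosages are mean-imputed per site; SNPs collinear with the
#' fixed effects (e.g. monomorphic) are flagged missing.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effect design (intercept, sex, leading PCs, ...).
#' @param K Kinship matrix.
#' @param dosage Dosage matrix, sites x samples (samples aligned with `y`).
#' @param vc Optional output of [reml_null()]; computed if absent.
#' @return Data frame per SNP: `beta`, `se`, `t`, `p`, `mlog10p`.
#' @export
emmax_scan <- function(y, X, K, dosage, vc = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  if (is.null(vc)) vc <- reml_null(y, X, K)
  ek <- eigen(K, symmetric = TRUE)
  lam <- pmax(ek$values, 0)
  w <- 1 / sqrt(vc$sigma_g2 * lam + vc$sigma_e2)
  Ut <- t(ek$vectors)
  ty <- w * as.vector(Ut %*% y)
  tX <- w * (Ut %*% X)

  rm <- rowMeans(dosage, na.rm = TRUE)
  if (anyNA(dosage)) {
    miss <- which(is.na(dosage), arr.ind = TRUE)
    dosage[miss] <- rm[miss[, 1L]]
  }
  tG <- w * (Ut %*% t(dosage))          # n x m rotated dosages

  m <- nrow(dosage)
  beta <- se <- tv <- pv <- rep(NA_real_, m)
  p_fixed <- ncol(tX)
  for (j in seq_len(m)) {
    Z <- cbind(tX, tG[, j])
    qz <- qr(Z)
    if (qz$rank < p_fixed + 1L) next    # collinear / monomorphic
    fit <- qr.coef(qz, ty)
    res <- ty - Z %*% fit
    df <- n - qz$rank
    s2 <- sum(res^2) / df
    XtXinv <- solve(crossprod(Z))
    beta[j] <- fit[p_fixed + 1L]
    se[j] <- sqrt(s2 * XtXinv[p_fixed + 1L, p_fixed + 1L])
    tv[j] <- beta[j] / se[j]
    pv[j] <- 2 * pt(abs(tv[j]), df, lower.tail = FALSE)
  }
  data.frame(beta = beta, se = se, t = tv, p = pv, mlog10p = -log10(pv))
}

#' Bonferroni genome-wide significance cutoff
#'
#' Family-wise threshold `alpha / n_tests` expressed on the -log10 p scale:
#' `log10(n_tests / alpha)`.
#'
#' @param n_tests Number of tested SNPs.
#' @param alpha Family-wise error rate (default 0.01).
#' @return -log10 p cutoff.
#' @examples
#' bonferroni_threshold(1, 0.01) # 2
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.01) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  log10(n_tests / alpha)
}

#' Overlap associated SNPs with candidate regions
#'
#' Keeps the candidate regions containing at least one SNP at or above the
#' significance cutoff and attaches the qualifying SNPs.
#'
#' @param assoc Data frame `chrom`, `pos`, `mlog10p` (one row per SNP).
#' @param regions Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param cutoff -log10 p cutoff (e.g. [bonferroni_threshold()]).
#' @return List with `regions` (qualifying regions plus `n_sig`) and
#'   `snps` (qualifying SNPs with their region).
#' @export
overlap_assoc_with_regions <- function(assoc, regions, cutoff) {
  sig <- assoc[!is.na(assoc$mlog10p) & assoc$mlog10p >= cutoff, , drop = FALSE]
  keep <- logical(nrow(regions))
  n_sig <- integer(nrow(regions))
  hits <- list()
  for (r in seq_len(nrow(regions))) {
    inr <- sig$chrom == regions$chrom[r] &
      (sig$pos - 1L) >= regions$start[r] & (sig$pos - 1L) < regions$end[r]
    n_sig[r] <- sum(inr)
    keep[r] <- n_sig[r] > 0L
    if (keep[r]) {
      h <- sig[inr, , drop = FALSE]
      h$region <- r
      hits[[length(hits) + 1L]] <- h
    }
  }
  out_regions <- regions[keep, , drop = FALSE]
  out_regions$n_sig <- n_sig[keep]
  snps <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(0), pos = integer(0),
               mlog10p = numeric(0), region = integer(0))
  rownames(out_regions) <- rownames(snps) <- NULL
  list(regions = out_regions, snps = snps)
}
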