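# Independent brute-force oracles, written straight from the defining
# formulas. They deliberately share no code with the package internals:
# scalar loops, explicit enumeration, no vectorized shortcuts.

# Weir & Cockerham (1984) two-population variance components for one site,
# from first principles: sample sizes n_i, allele frequencies p_i and
# heterozygote frequencies h_i.
wc84_oracle <- function(gen_a, gen_b) {
  gen_a <- gen_a[!is.na(gen_a)]
  gen_b <- gen_b[!is.na(gen_b)]
  n <- c(length(gen_a), length(gen_b))
  p <- c(sum(gen_a) / (2 * n[1]), sum(gen_b) / (2 * n[2]))
  h <- c(mean(gen_a == 1), mean(gen_b == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, d = a + b + cc)
}

# EHH at every flanking site by explicit haplotype-string comparison.
ehh_oracle_side <- function(hap, core, carriers, dir, cutoff = 0.05) {
  nc <- length(carriers)
  out <- numeric(0)
  j <- core + dir
  while (j >= 1 && j <= ncol(hap)) {
    rng <- if (dir > 0) core:j else j:core
    keys <- apply(hap[carriers, rng, drop = FALSE], 1, paste, collapse = "")
    counts <- table(keys)
    e <- sum(choose(counts, 2)) / choose(nc, 2)
    out <- c(out, e)
    if (e < cutoff) break
    j <- j + dir
  }
  out
}

# iHH by explicit trapezoid sums over the curve truncated at the last
# point >= cutoff on each side.
ihh_oracle <- function(hap, positions, core, cutoff = 0.05) {
  carriers <- seq_len(nrow(hap))
  core_counts <- table(hap[, core])
  core_hom <- sum(choose(core_counts, 2)) / choose(nrow(hap), 2)
  total <- 0
  for (dir in c(1, -1)) {
    e <- ehh_oracle_side(hap, core, carriers, dir, cutoff)
    keep <- which(e >= cutoff)
    if (!length(keep)) next
    last <- max(keep)
    xs <- positions[core + dir * (0:last)]
    ys <- c(core_hom, e[seq_len(last)])
    for (k in seq_len(last))
      total <- total + abs(xs[k + 1] - xs[k]) * (ys[k] + ys[k + 1]) / 2
  }
  total
}

# Nucleotide diversity: mean pairwise Hamming distance over all haplotype
# pairs, divided by the window length.
pi_oracle <- function(hap, window_len) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2) / window_len
}

# 2x2 chi-squared statistic from the closed form (ad - bc)^2 N / products.
chisq_2x2_oracle <- function(m) {
  (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 * sum(m) /
    (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
}

# r-squared from explicit haplotype counting on phased data.
r2_oracle_phased <- function(hap_a, hap_b) {
  pA <- mean(hap_a == 0); pB <- mean(hap_b == 0)
  pAB <- mean(hap_a == 0 & hap_b == 0)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Dense GLS: explicit inverse of V = sg2 K + se2 I, coefficient and t-test
# for the last column of the design.
gls_dense_oracle <- function(y, Z, K, sg2, se2) {
  V <- sg2 * K + se2 * diag(length(y))
  Vi <- solve(V)
  XtVi <- t(Z) %*% Vi
  C <- solve(XtVi %*% Z)
  bhat <- C %*% XtVi %*% y
  resid <- y - Z %*% bhat
  df <- length(y) - ncol(Z)
  s2 <- as.numeric(t(resid) %*% Vi %*% resid) / df
  j <- ncol(Z)
  se <- sqrt(s2 * C[j, j])
  tv <- bhat[j] / se
  list(beta = bhat[j], se = se, t = tv,
       p = 2 * pt(abs(tv), df, lower.tail = FALSE))
}

# Restricted log-likelihood evaluated from the matrix definition, up to
# the REML constant: -0.5 [ log|V| + log|X'V^-1 X| + y' P y ] with
# P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1 and V = K + delta I (sigma_g^2
# profiled out would change this; used only for relative comparisons).
reml_ll_dense <- function(y, X, K, sg2, se2) {
  V <- sg2 * K + se2 * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  n <- length(y); q <- ncol(X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y) -
               0.5 * (n - q) * log(2 * pi) +
               0.5 * determinant(crossprod(X))$modulus)
}
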