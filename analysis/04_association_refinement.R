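#!/usr/bin/env Rscript
# Stage 4 — mixed-model association on breast muscle weight (EMMAX
# approximation: kinship + spectral REML once, per-SNP GLS), Bonferroni
# thresholding, overlap with the scan's candidate regions, LD-based
# refinement of the surviving regions, and allele-frequency trajectories
# of the top SNPs.

library(tempsel)

data_dir <- "results/data"
out <- "results/gwas"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vt <- suppressWarnings(filter_variants(
  read_vcf(file.path(data_dir, "genotypes.vcf"))$genotypes,
  "discovery"))$table
meta <- read_tsv(file.path(data_dir, "samples.tsv"))
pheno <- read_tsv(file.path(data_dir, "phenotypes.tsv"))
regions <- tryCatch(read_tsv("results/scan/candidate_regions.tsv"),
                    error = function(e) NULL)

y <- pheno$BMW[match(vt$samples, pheno$sample_id)]
sex <- as.integer(meta$sex[match(vt$samples, meta$sample_id)] == "M")
pca <- genotype_pca(vt$dosage, k = 3L)
X <- cbind(intercept = 1, sex = sex, pca$scores)
K <- kinship_matrix(vt$dosage)
vc <- reml_null(y, X, K)
cat(sprintf("null model: sigma_g2 = %.1f, sigma_e2 = %.1f (ratio %.2f)\n",
            vc$sigma_g2, vc$sigma_e2, vc$h2))

assoc <- cbind(vt$sites[, c("chrom", "pos")],
               emmax_scan(y, X, K, vt$dosage, vc = vc))
write_tsv(assoc, file.path(out, "assoc.tsv"))
cutoff <- bonferroni_threshold(sum(!is.na(assoc$p)), 0.01)
n_sig <- sum(assoc$mlog10p >= cutoff, na.rm = TRUE)
top <- assoc[which.max(assoc$mlog10p), ]
cat(sprintf("Bonferroni cutoff -log10 p = %.2f; %d significant SNP(s); top %s:%d (%.2f)\n",
            cutoff, n_sig, top$chrom, top$pos, top$mlog10p))

if (!is.null(regions) && nrow(regions)) {
  ov <- overlap_assoc_with_regions(assoc, regions, cutoff)
  cat(sprintf("%d candidate region(s) contain a genome-wide significant SNP\n",
              nrow(ov$regions)))
  to_refine <- if (nrow(ov$regions)) ov$regions else regions
  refined <- NULL
  for (r in seq_len(nrow(to_refine))) {
    reg <- to_refine[r, ]
    idx <- which(vt$sites$chrom == reg$chrom &
                   vt$sites$pos - 1 >= reg$start &
                   vt$sites$pos - 1 < reg$end)
    if (!length(idx)) next
    lead <- lead_snp(vt$sites$pos[idx], assoc$mlog10p[idx])
    r2 <- r2_to_lead(vt$dosage[idx, , drop = FALSE], lead)
    rf <- refine_region(vt$sites$pos[idx], r2, lead, 0.4)
    refined <- rbind(refined, data.frame(
      chrom = reg$chrom, start = rf$start, end = rf$end,
      lead_pos = vt$sites$pos[idx][lead], n_snps = rf$n_snps))
  }
  if (!is.null(refined)) {
    write_tsv(refined, file.path(out, "refined_regions.tsv"))
    cat(sprintf("refined %d region(s) (r2 > 0.4 envelope) spanning %.0f bp\n",
                nrow(refined), region_span(refined)))
    # trajectories of the lead SNPs across the sampled generations
    lead_idx <- match(paste(refined$chrom, refined$lead_pos),
                      paste(vt$sites$chrom, vt$sites$pos))
    tr <- frequency_trajectory(vt, meta, lead_idx)
    write_tsv(tr, file.path(out, "lead_snp_trajectories.tsv"))
  }
} else {
  cat("no candidate regions from the scan stage; nothing to overlap\n")
}
cat("association tables written to", out, "\n")
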