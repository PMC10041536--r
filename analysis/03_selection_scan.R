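#!/usr/bin/env Rscript
# Stage 3 — joint selection scan: Weir-Cockerham Fst and XP-EHH in 10-kb
# windows with 5-kb steps between the first and last cohorts, empirical
# top-1% thresholds, candidate-region intersection, and windowed
# nucleotide diversity per cohort.

library(tempsel)

data_dir <- "results/data"
out <- "results/scan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vt <- read_vcf(file.path(data_dir, "genotypes.vcf"))$genotypes
meta <- read_tsv(file.path(data_dir, "samples.tsv"))
flt <- suppressWarnings(filter_variants(vt, "discovery"))
vt <- flt$table
cat(sprintf("discovery filter kept %d of %d sites\n", flt$n_kept, flt$n_input))

g_ref <- min(meta$generation); g_query <- max(meta$generation)
ids_ref <- meta$sample_id[meta$generation == g_ref]
ids_query <- meta$sample_id[meta$generation == g_query]
chrom_lengths <- tapply(vt$sites$pos, vt$sites$chrom, max)

comps <- wc_fst_site(vt$dosage[, match(ids_ref, vt$samples)],
                     vt$dosage[, match(ids_query, vt$samples)])
fst_win <- fst_windows(vt$sites, comps, 10000, 5000, chrom_lengths)
write_tsv(fst_win, file.path(out, "fst_windows.tsv"))

xp <- xpehh_scan(vt, ids_ref, ids_query)
xp_win <- xpehh_windows(xp, 10000, 5000, chrom_lengths)
write_tsv(xp, file.path(out, "xpehh_sites.tsv"))
write_tsv(xp_win, file.path(out, "xpehh_windows.tsv"))

fst_cut <- suppressWarnings(empirical_threshold(fst_win$value, 0.01, "upper"))
xp_cut <- suppressWarnings(empirical_threshold(xp_win$value, 0.01, "two"))
cat(sprintf("top-1%% thresholds: Fst %.3f, XP-EHH %.3f / %.3f\n",
            fst_cut["upper"], xp_cut["lower"], xp_cut["upper"]))

fst_above <- fst_win[fst_win$value >= fst_cut["upper"], ]
xp_above <- xp_win[xp_win$value >= xp_cut["upper"] |
                     xp_win$value <= xp_cut["lower"], ]
regions <- intersect_candidate_windows(fst_above, xp_above)
write_tsv(regions, file.path(out, "candidate_regions.tsv"))
cat(sprintf("%d Fst and %d XP-EHH windows above threshold -> %d candidate region(s), %.0f bp\n",
            nrow(fst_above), nrow(xp_above), nrow(regions),
            if (nrow(regions)) region_span(regions) else 0))

for (side in c("ref", "query")) {
  ids <- if (side == "ref") ids_ref else ids_query
  j <- match(ids, vt$samples)
  hap <- t(vt$haplotypes[, as.vector(rbind(2 * j - 1, 2 * j))])
  pw <- nucleotide_diversity(hap, vt$sites, 10000, 5000, chrom_lengths)
  write_tsv(pw, file.path(out, sprintf("pi_%s.tsv", side)))
  assign(paste0("pi_", side), mean(pw$value))
}
cat(sprintf("mean nucleotide diversity: %.3g (G%d) vs %.3g (G%d); ratio %.2f\n",
            pi_ref, g_ref, pi_query, g_query, pi_query / pi_ref))
cat("scan tables written to", out, "\n")
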