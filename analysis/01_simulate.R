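#!/usr/bin/env Rscript
# Stage 1 — simulate the closed breeding line and write every input the
# downstream analyses consume (VCF, sample metadata, phenotypes,
# annotation track, copy-number matrix, and the simulation ground truth).

library(tempsel)

seed <- 4L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

sim <- run_breeding_simulation(cfg)
means <- vapply(sim$populations, function(p) mean(p$phenotype), 0)
cat(sprintf("mean breast muscle weight: %.1f g (G1) -> %.1f g (G%d)\n",
            means[1], means[length(means)], length(means)))

set.seed(seed + 1L)
cohorts <- sample_cohorts(sim)
cat(sprintf("sampled %d individuals across generations %s\n",
            nrow(cohorts$meta),
            paste(sort(unique(cohorts$meta$generation)), collapse = ", ")))

write_vcf(cohorts$genotypes, file.path(out, "genotypes.vcf"))
write_tsv(cohorts$meta, file.path(out, "samples.tsv"))
write_tsv(cohorts$phenotypes, file.path(out, "phenotypes.tsv"))

annot <- make_annotation_track(sim$populations[[1]]$chrom_lengths)
write_bed(annot, file.path(out, "annotation.bed"))

set.seed(seed + 2L)
cn <- simulate_cnv_matrix(cohorts$meta,
                          chrom_lengths = sim$populations[[1]]$chrom_lengths)
write_tsv(cbind(cn$cnvrs[, c("cnvr_id", "chrom", "start", "end")],
                as.data.frame(cn$values)),
          file.path(out, "cn_matrix.tsv"))

truth <- export_truth(sim)
write_tsv(truth$causal, file.path(out, "causal_truth.tsv"))
write_tsv(data.frame(index = seq_len(nrow(truth$trajectories)),
                     truth$trajectories),
          file.path(out, "true_trajectories.tsv"))

shift <- abs(truth$trajectories[, ncol(truth$trajectories)] -
               truth$trajectories[, 1])
cat(sprintf("true allele-frequency shifts: causal mean %.2f, neutral mean %.2f, max %.2f\n",
            mean(shift[truth$causal$index]),
            mean(shift[-truth$causal$index]), max(shift)))
cat("inputs written to", out, "\n")
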