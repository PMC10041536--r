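#' Pipeline configuration
#'
#' Collects the thresholds of the full generation-resolved analysis:
#' comparison cohorts (default generations 1 vs 10), 10-kb/5-kb scan
#' windows, top-1% scan tails, GWAS family-wise alpha 0.01, LD refinement
#' r-squared 0.4 and the CNV top-5% screen, together with either a
#' simulation block (the default) or paths to existing inputs.
#'
#' @param sim A [sim_config()] describing the simulated inputs, or `NULL`
#'   when `paths` are given.
#' @param paths Optional named list (`vcf`, `meta`, `pheno`, `annot`,
#'   `cn_matrix`) of existing input files; overrides `sim`.
#' @param generations Comparison cohorts, reference first.
#' @param window,step Scan window geometry (bp).
#' @param scan_tail,cnv_tail Empirical-quantile tails.
#' @param gwas_alpha Family-wise error rate for the Bonferroni cutoff.
#' @param r2_threshold LD refinement threshold.
#' @param cnv Run the CNV branch?
#' @param n_cnvr Number of CNVRs simulated for the CNV branch.
#' @param seed Master seed; every stage draws its own sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            generations = c(1L, 10L),
                            window = 10000, step = 5000,
                            scan_tail = 0.01, cnv_tail = 0.05,
                            gwas_alpha = 0.01, r2_threshold = 0.4,
                            cnv = TRUE, n_cnvr = 81L, seed = 1L) {
  stopifnot(scan_tail > 0, scan_tail < 1, cnv_tail > 0, cnv_tail < 1,
            gwas_alpha > 0, gwas_alpha < 1, r2_threshold > 0, r2_threshold < 1)
  if (is.null(sim) && is.null(paths))
    stop("config error: provide a simulation block or input paths",
         call. = FALSE)
  structure(list(sim = sim, paths = paths, generations = generations,
                 window = window, step = step, scan_tail = scan_tail,
                 cnv_tail = cnv_tail, gwas_alpha = gwas_alpha,
                 r2_threshold = r2_threshold, cnv = cnv, n_cnvr = n_cnvr,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; a `sim:` block mirrors
#' [sim_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else
    if (is.null(y$paths)) sim_config() else NULL
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Run the full generation-resolved selection analysis
#'
#' Executes, in dependency order: simulation (or input loading), cohort
#' sampling, variant filtering, PCA, the temporal allele-frequency
#' difference branch (binning + annotation enrichment), the joint
#' Fst/XP-EHH window scan with top-quantile intersection into candidate
#' regions, the mixed-model association scan with Bonferroni cutoff and
#' region overlap, LD refinement of the overlapped regions, diversity and
#' trajectory tracking, and the CNV RFD screen. All randomness flows from
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, intermediates (VCF, TSV,
#'   BED) and the report (JSON + Markdown) are persisted there.
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: `report` (headline numbers) plus all
#'   intermediate tables.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  stage_seed <- sample.int(2147483646L, 8L)

  # --- stage 1: inputs -------------------------------------------------
  if (!is.null(config$paths)) {
    p <- config$paths
    vt <- read_vcf(p$vcf)$genotypes
    meta <- read_tsv(p$meta)
    pheno <- read_tsv(p$pheno)
    annot <- read_bed(p$annot)
    cn <- if (!is.null(p$cn_matrix)) {
      m <- read_tsv(p$cn_matrix)
      vals <- as.matrix(m[, setdiff(names(m), c("cnvr_id", "chrom", "start", "end")),
                          drop = FALSE])
      rownames(vals) <- m$cnvr_id
      list(values = vals,
           cnvrs = m[, c("cnvr_id", "chrom", "start", "end")])
    } else NULL
    truth <- NULL
    chrom_lengths <- tapply(vt$sites$pos, vt$sites$chrom, max)
  } else {
    simcfg <- config$sim
    simcfg$seed <- stage_seed[1]
    say("simulating %d generations ...", simcfg$n_generations)
    sim <- run_breeding_simulation(simcfg)
    set.seed(stage_seed[2])
    cohorts <- sample_cohorts(sim)
    vt <- cohorts$genotypes
    meta <- cohorts$meta
    pheno <- cohorts$phenotypes
    annot <- make_annotation_track(sim$populations[[1]]$chrom_lengths)
    truth <- export_truth(sim)
    chrom_lengths <- sim$populations[[1]]$chrom_lengths
    cn <- if (config$cnv) {
      set.seed(stage_seed[3])
      simulate_cnv_matrix(meta, n_cnvr = config$n_cnvr,
                          n_generations = simcfg$n_generations,
                          chrom_lengths = chrom_lengths)
    } else NULL
  }
  g_ref <- config$generations[1]; g_query <- config$generations[2]
  ids_ref <- meta$sample_id[meta$generation == g_ref]
  ids_query <- meta$sample_id[meta$generation == g_query]

  # --- stage 2: filtering ---------------------------------------------
  say("filtering %d sites ...", n_sites(vt))
  flt_scan <- suppressWarnings(filter_variants(vt, "discovery"))
  flt_afd <- suppressWarnings(filter_variants(vt, "afd"))
  vt_scan <- flt_scan$table
  vt_afd <- flt_afd$table

  # --- stage 3: structure + dAF branch --------------------------------
  pca <- genotype_pca(vt_scan$dosage, k = 3L)
  afd <- delta_af_cohorts(vt_afd, meta, config$generations)
  afd_inf <- afd[afd$informative, , drop = FALSE]
  bins <- bin_delta_af(afd_inf$delta_af)
  categories <- intersect_with_annotation(afd_inf, annot)
  enrichment <- category_enrichment(bins, categories)

  # --- stage 4: joint selection scan ----------------------------------
  say("scanning Fst / XP-EHH ...")
  dref <- vt_scan$dosage[, match(ids_ref, vt_scan$samples), drop = FALSE]
  dquery <- vt_scan$dosage[, match(ids_query, vt_scan$samples), drop = FALSE]
  comps <- wc_fst_site(dref, dquery)
  fst_win <- fst_windows(vt_scan$sites, comps, config$window, config$step,
                         chrom_lengths)
  xp <- xpehh_scan(vt_scan, ids_ref, ids_query)
  xp_win <- xpehh_windows(xp, config$window, config$step, chrom_lengths)
  fst_cut <- suppressWarnings(
    empirical_threshold(fst_win$value, config$scan_tail, "upper"))
  xp_cut <- suppressWarnings(
    empirical_threshold(xp_win$value, config$scan_tail, "two"))
  fst_above <- fst_win[fst_win$value >= fst_cut["upper"], , drop = FALSE]
  xp_above <- xp_win[xp_win$value >= xp_cut["upper"] |
                       xp_win$value <= xp_cut["lower"], , drop = FALSE]
  candidates <- intersect_candidate_windows(fst_above, xp_above)

  # --- stage 5: mixed-model association -------------------------------
  say("mixed-model scan over %d SNPs ...", n_sites(vt_scan))
  ord <- match(vt_scan$samples, pheno$sample_id)
  y <- pheno$BMW[ord]
  sex <- as.integer(meta$sex[match(vt_scan$samples, meta$sample_id)] == "M")
  X <- cbind(intercept = 1, sex = sex, pca$scores)
  K <- kinship_matrix(vt_scan$dosage)
  vc <- reml_null(y, X, K)
  assoc <- cbind(vt_scan$sites[, c("chrom", "pos")],
                 emmax_scan(y, X, K, vt_scan$dosage, vc = vc))
  gwas_cut <- bonferroni_threshold(sum(!is.na(assoc$p)), config$gwas_alpha)
  overlap <- overlap_assoc_with_regions(assoc, candidates, gwas_cut)

  # --- stage 6: LD refinement -----------------------------------------
  # refine the Bonferroni-overlapped regions when any exist; otherwise
  # fall back to the scan's candidate regions, each led by its most
  # associated SNP (the refinement is then exploratory)
  refine_set <- if (nrow(overlap$regions)) overlap$regions else candidates
  refined_source <- if (nrow(overlap$regions)) "overlap" else "candidates"
  refined <- list()
  for (r in seq_len(nrow(refine_set))) {
    reg <- refine_set[r, ]
    in_reg <- which(vt_scan$sites$chrom == reg$chrom &
                      vt_scan$sites$pos - 1L >= reg$start &
                      vt_scan$sites$pos - 1L < reg$end)
    if (!length(in_reg)) next
    scores <- assoc$mlog10p[in_reg]
    lead_local <- lead_snp(vt_scan$sites$pos[in_reg], scores)
    r2 <- r2_to_lead(vt_scan$dosage[in_reg, , drop = FALSE], lead_local)
    rf <- refine_region(vt_scan$sites$pos[in_reg], r2, lead_local,
                        config$r2_threshold)
    refined[[length(refined) + 1L]] <- data.frame(
      chrom = reg$chrom, start = rf$start, end = rf$end,
      lead_pos = vt_scan$sites$pos[in_reg][lead_local],
      n_snps = rf$n_snps, degenerate = rf$degenerate)
  }
  refined <- if (length(refined)) do.call(rbind, refined) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               lead_pos = numeric(0), n_snps = integer(0),
               degenerate = logical(0))
  attr(refined, "source") <- refined_source

  # --- stage 7: diversity + trajectories ------------------------------
  hap_ref <- t(vt_scan$haplotypes[, hap_col_index(vt_scan, ids_ref), drop = FALSE])
  hap_query <- t(vt_scan$haplotypes[, hap_col_index(vt_scan, ids_query), drop = FALSE])
  pi_ref <- nucleotide_diversity(hap_ref, vt_scan$sites, config$window,
                                 config$step, chrom_lengths)
  pi_query <- nucleotide_diversity(hap_query, vt_scan$sites, config$window,
                                   config$step, chrom_lengths)
  sig_idx <- which(!is.na(assoc$mlog10p) & assoc$mlog10p >= gwas_cut)
  trajectories <- if (length(sig_idx))
    frequency_trajectory(vt_scan, meta, sig_idx) else NULL

  # --- stage 8: CNV branch --------------------------------------------
  cnv_res <- NULL
  if (!is.null(cn)) {
    say("CNV screen over %d CNVRs ...", nrow(cn$values))
    screen <- cnv_screen(cn$values, meta, config$generations,
                         tail_fraction = config$cnv_tail)
    classes <- classify_copy_number(cn$values)
    sel <- which(screen$selected)
    cls_traj <- if (length(sel))
      cnv_frequency_trajectory(classes[sel, , drop = FALSE], meta) else NULL
    # trait variance explained by the strongest-shifting usable CNVR
    pass <- which(screen$qc_pass & !is.na(screen$rfd))
    r2_top <- NA_real_
    if (length(pass)) {
      top <- pass[which.max(abs(screen$rfd[pass]))]
      ord_cn <- match(colnames(cn$values), pheno$sample_id)
      r2_top <- cnv_variance_explained(classes[top, ], pheno$BMW[ord_cn])
    }
    cnv_res <- list(screen = screen, cutoff = attr(screen, "cutoff"),
                    trajectories = cls_traj, top_variance_explained = r2_top,
                    cnvrs = cn$cnvrs)
  }

  res <- list(
    config = config, meta = meta, phenotypes = pheno,
    filters = list(scan = flt_scan[c("rejections", "n_input", "n_kept")],
                   afd = flt_afd[c("rejections", "n_input", "n_kept")]),
    pca = pca, afd = afd, enrichment = enrichment,
    fst_windows = fst_win, xpehh = xp, xpehh_windows = xp_win,
    thresholds = list(fst = unname(fst_cut["upper"]),
                      xpehh_lower = unname(xp_cut["lower"]),
                      xpehh_upper = unname(xp_cut["upper"]),
                      gwas = gwas_cut),
    candidates = candidates, assoc = assoc, overlap = overlap,
    refined = refined, pi_ref = pi_ref, pi_query = pi_query,
    trajectories = trajectories, cnv = cnv_res, truth = truth,
    genotypes = vt_scan
  )
  res$report <- make_report(res)
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) persist_pipeline(res, vt, annot, cn, out_dir)
  res
}

hap_col_index <- function(vt, ids) {
  j <- match(ids, vt$samples)
  as.vector(rbind(2L * j - 1L, 2L * j))
}

#' Headline report of a pipeline run
#'
#' Summarizes a run into the numbers mirroring the emulated study's result
#' structure: cohort sizes, filter outcomes, realized scan thresholds,
#' candidate/overlapped/refined region counts and spans, significant SNP
#' count, the largest temporal allele-frequency shift, diversity change,
#' and the CNV screen outcome. Regenerable from the persisted
#' intermediates; every count is traceable to a stage output.
#'
#' @param res A `pipeline_result` (or the intermediate list during a run).
#' @return A named list of headline values.
#' @export
make_report <- function(res) {
  span <- function(df) if (is.null(df) || !nrow(df)) 0 else
    suppressWarnings(region_span(df))
  cnv_n <- if (is.null(res$cnv)) NA_integer_ else sum(res$cnv$screen$selected)
  list(
    n_samples = nrow(res$meta),
    n_snps_scan = nrow(res$assoc),
    filter_rejections = as.list(res$filters$scan$rejections),
    thresholds = res$thresholds,
    max_delta_af = max(res$afd$delta_af, na.rm = TRUE),
    n_candidate_regions = nrow(res$candidates),
    candidate_span_bp = span(res$candidates),
    n_significant_snps = sum(!is.na(res$assoc$mlog10p) &
                               res$assoc$mlog10p >= res$thresholds$gwas),
    n_overlapped_regions = nrow(res$overlap$regions),
    overlapped_span_bp = span(res$overlap$regions),
    n_refined_regions = nrow(res$refined),
    refined_span_bp = span(res$refined),
    refined_source = attr(res$refined, "source") %||% "overlap",
    mean_pi_ref = mean(res$pi_ref$value),
    mean_pi_query = mean(res$pi_query$value),
    n_cnvr_selected = cnv_n,
    cnv_rfd_cutoff = if (is.null(res$cnv)) NA_real_ else res$cnv$cutoff,
    cnv_top_variance_explained = if (is.null(res$cnv)) NA_real_ else
      res$cnv$top_variance_explained,
    cnv_skipped = is.null(res$cnv),
    seed = res$config$seed
  )
}

persist_pipeline <- function(res, vt, annot, cn, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_vcf(vt, fp("genotypes.vcf"))
  write_tsv(res$meta, fp("samples.tsv"))
  write_tsv(res$phenotypes, fp("phenotypes.tsv"))
  write_bed(annot, fp("annotation.bed"))
  write_tsv(res$fst_windows, fp("fst_windows.tsv"))
  write_tsv(res$xpehh_windows, fp("xpehh_windows.tsv"))
  write_tsv(res$assoc, fp("assoc.tsv"))
  write_tsv(res$enrichment, fp("afd_enrichment.tsv"))
  if (nrow(res$candidates))
    write_tsv(res$candidates, fp("candidate_regions.tsv"))
  if (nrow(res$refined)) write_tsv(res$refined, fp("refined_regions.tsv"))
  if (!is.null(cn)) {
    m <- cbind(cn$cnvrs[, c("cnvr_id", "chrom", "start", "end")],
               as.data.frame(cn$values))
    write_tsv(m, fp("cn_matrix.tsv"))
    write_tsv(res$cnv$screen, fp("cnv_screen.tsv"))
  }
  write_report(res$report, out_dir)
  invisible(out_dir)
}

#' Write a run report as JSON and Markdown
#'
#' @param report Output of [make_report()].
#' @param out_dir Target directory.
#' @return Paths of the two files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mp <- file.path(out_dir, "report.md")
  lines <- c(
    "# Selection-signature run report", "",
    sprintf("- samples: %d", report$n_samples),
    sprintf("- SNPs in scan: %d", report$n_snps_scan),
    sprintf("- max temporal allele-frequency shift: %.3f", report$max_delta_af),
    sprintf("- Fst top-quantile threshold: %.4f", report$thresholds$fst),
    sprintf("- XP-EHH thresholds: %.3f / %.3f", report$thresholds$xpehh_lower,
            report$thresholds$xpehh_upper),
    sprintf("- candidate regions (Fst x XP-EHH): %d covering %.0f bp",
            report$n_candidate_regions, report$candidate_span_bp),
    sprintf("- GWAS cutoff (-log10 p): %.2f; significant SNPs: %d",
            report$thresholds$gwas, report$n_significant_snps),
    sprintf("- overlapped regions: %d covering %.0f bp",
            report$n_overlapped_regions, report$overlapped_span_bp),
    sprintf("- refined regions: %d covering %.0f bp",
            report$n_refined_regions, report$refined_span_bp),
    sprintf("- mean pi: %.3g (reference) vs %.3g (query)",
            report$mean_pi_ref, report$mean_pi_query),
    if (report$cnv_skipped) "- CNV branch: skipped (no input)" else
      sprintf("- CNVRs selected: %d (|RFD| cutoff %.2f); top CNVR explains %.1f%% of the trait variance",
              report$n_cnvr_selected, report$cnv_rfd_cutoff,
              100 * report$cnv_top_variance_explained)
  )
  writeLines(lines, mp)
  invisible(c(jp, mp))
}
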