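---
title: "Dissecting ten generations of truncation selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting ten generations of truncation selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tempsel` implements a generation-resolved analysis of a closed breeding
line under intense artificial selection on breast muscle weight, driven
entirely by a forward-time simulator so that no external data are needed.
This vignette is the package's account of the science: the models, their
assumptions, the parameters that matter, and what the simulation-based
tests do and do not establish about real data.

## The breeding design being emulated

The emulated design is a closed duck line of roughly 750 individuals per
generation, selected for ten generations by sex-specific phenotypic
truncation: about 37.5% of females and 7.5% of males with the heaviest
breast muscle are retained as parents. Cohorts of 15 males and 15 females
are sampled at generations 1, 4, 7 and 10, with one generation-4 sample
lost, giving 119 sequenced individuals. Breast muscle weight (BMW, grams)
is measured indirectly: breast breadth (BB), keel length (KL) and breast
muscle thickness (BMT) give a volume BMV = BB x KL x BMT, and
BMW = 0.6228 x BMV + 17.042.

The retention scheme fixes the line's drift regime: with 375 candidates
per sex, truncation keeps 29 sires and 141 dams, so the variance effective
size is Ne = 4 Nm Nf / (Nm + Nf) = 96. Over nine transmissions that
predicts per-generation allele-frequency variance p(1-p)/192 and a
pairwise identity-by-descent probability of roughly t/(2Ne) = 4.7% by
generation 10 — both properties are verified against the simulator in the
test suite.

## The forward simulator

`sim_config()` / `run_breeding_simulation()` implement a diploid
Wright-Fisher model with:

* **Truncation selection.** Each sex is ranked by phenotype and the top
  `ceiling(retention x N)` kept. Offspring draw a dam and a sire uniformly
  with replacement from the retained sets (selfing is impossible; fuller
  inbreeding avoidance is not modelled).
* **Meiosis.** Poisson crossovers per chromosome at `recomb_rate`
  (default 3e-8 per bp, i.e. 3 cM/Mb, a typical avian macro-chromosome
  rate) with uniform positions and no interference.
* **Trait model.** BMW is simulated directly as genetic value plus
  Gaussian noise; the measurement components BB/KL/BMT are back-filled for
  I/O realism only (BB = KL = 10 cm reference, BMT carries the volume).
  Effect sizes are relative weights rescaled once so that the founder
  additive variance equals `h2 * pheno_sd^2`; the environmental standard
  deviation is then frozen, so heritability is a founder-generation
  property and erodes as selection exhausts variance — which is the point
  of tracking it.

### Founder haplotypes: a mosaic ancestry pool

Founder haplotypes are mosaics over a small pool of ancestral haplotypes
(`n_founder_haplotypes = 12`), with ancestry blocks of exponential length
(`founder_block_bp = 5e4`). This is the coalescent-style block structure
of a bottlenecked source population: background LD decays on the ~50-kb
scale (as for a historical effective size in the low thousands at 3
cM/Mb), while baseline haplotype homozygosity is 1/12 = 0.083. Both
matter: hitchhiking around a selected allele extends over roughly one
ancestry-block scale, so selection signatures localize, and the
haplotype-homozygosity statistics have a finite baseline to contrast
against. Setting `n_founder_haplotypes = NULL` draws founder alleles
independently per locus (no background LD), which is the right null for
drift calibration but useless for haplotype statistics. Causal loci are
forced to segregate in the pool at their configured frequency; with a
12-haplotype pool, unconditional Bernoulli draws would silently fix about
a quarter of them.

### Trait architecture defaults, and why

Ten causal loci of **equal magnitude** (all trait-increasing, founder
frequency uniform on 0.1-0.3) with founder h2 = 0.3 and phenotypic SD
32 g around a founder mean of 80 g. The reasoning, fixed before the
pipeline was evaluated:

* h2 = 0.3 is the conventional assumption for a meat-yield trait absent a
  published estimate for this line.
* The phenotypic SD is back-derived from the emulated study's printed
  response (80 g to 220 g over ten generations) through the breeder's
  equation R = h2 * i * sd at the design's selection intensity
  (i = (1.89 + 1.01)/2 = 1.45).
* Equal effects keep every causal locus responding across all ten
  generations (a polygenic, soft-sweep regime, consistent with the
  emulated study's interpretation and its observation that no SNP shifted
  by more than 0.55). A geometric series (`effect_decay < 1`) is
  available to model a major-gene architecture; it produces earlier
  near-fixation of the top locus and a faster plateau.

With these defaults the simulated line's mean BMW rises from ~80 g to
~220 g, causal allele-frequency shifts average ~0.6 without fixation from
interior frequencies, and genome-wide diversity declines by 10-20% —
matching the qualitative fingerprints of the emulated study.

### Scaled-down genome

Three chromosomes of 5 Mb with 3,000 SNPs (one per 5 kb). These sizes
keep a full simulation-plus-analysis run under ~20 s on one CPU, so the
test suite can afford 20-replicate property studies; the trade-offs of
desk scale are discussed under *Limitations*.

## The analysis pipeline

`run_pipeline()` chains the stages; each is exported on its own.

**Filtering.** Two profiles mirror the emulated study's two filter sets:
`discovery` (3x < mean depth < 30x, MAF > 0.05, major-allele frequency
< 0.99, missing < 0.1) feeds the scans and the mixed model; `afd`
(missing <= 0.1, MAF > 0.01, 5x <= depth <= 30x) feeds the
allele-frequency-difference branch. All inequalities are exactly as
printed (a site at MAF 0.05 is removed by `discovery`). Rejection counts
attribute each site to its first failing criterion in the order depth,
max-AF, MAF, missingness; max-AF is tested before MAF because for a
biallelic site a failing major-allele frequency implies a failing MAF.
Depth criteria are skipped (with a warning) on simulated data without
depth annotations.

**Temporal allele-frequency differences.** dAF = |RefAF_last −
RefAF_first| per SNP, computed on non-missing alleles, binned in
left-closed 0.05-wide bins (the final bin closed at 1). Enrichment per
(bin, annotation category) uses M = log2((n_bc/n_b)/(n_c/n)) and a 2x2
chi-squared test without continuity correction, falling back to Fisher's
exact test when an expected cell is below 5 — the large-count regime the
chi-squared approximation assumes does not survive desk scale in sparse
bins. Sites monomorphic in both cohorts are excluded; no multiplicity
correction is applied across bins x categories (matching the emulated
analysis; a flag would be trivial to add).

**Joint selection scan.** Per-site Weir-Cockerham (1984) two-population
variance components, aggregated into 10-kb windows at 5-kb steps as the
ratio of sums (sum a / sum (a+b+c)); mean-of-site-Fst is available but
ratio-of-sums is the default, matching standard windowed-estimator
practice. XP-EHH integrates the combined-allele EHH curve (trapezoidal,
truncated where EHH drops below 0.05) in each cohort and takes
ln(iHH_query/iHH_ref) with the first generation as reference;
standardization is genome-wide. Haplotype identity includes the core-site
allele, so the combined curve starts at the core-site homozygosity —
selscan's convention. Window scores for XP-EHH are the **mean** of
standardized site values: per-site integrals are noisy at 60 haplotypes
per cohort, and taking the window's most extreme site (the alternative
`agg = "max"`) simply harvests that noise. Thresholds are empirical
type-7 quantiles: top 1% of Fst windows, both 1% tails of XP-EHH windows.
Candidate regions are the merged intersections of the two above-threshold
window sets.

**Mixed-model association.** y = Xb + g + e with X = intercept, sex and
the top 3 Patterson-normalized genotype PCs, g ~ N(0, sigma_g^2 K) for a
centered (VanRaden-style) kinship K rescaled to unit mean diagonal, and
e ~ N(0, sigma_e^2 I). The variance components are estimated once on the
null model by spectral REML — the restricted likelihood is profiled to
the single ratio delta = sigma_e^2/sigma_g^2 using the eigendecomposition
of S K S, scanned on a 41-point log grid over 10^-5..10^5 and refined by
bounded 1-D optimization — and then held fixed for every per-SNP
generalized-least-squares test (the EMMAX approximation). p-values use
the t distribution with n - rank([X, snp]) degrees of freedom rather than
the normal approximation; at n = 119 the difference is visible. Missing
dosages are mean-imputed per site. The genome-wide cutoff is Bonferroni
0.01/N on the actually tested SNP count. Candidate regions containing a
significant SNP are the final overlapped regions.

**LD refinement.** Within each surviving region the lead SNP (largest
-log10 p, ties to the smaller coordinate) anchors pairwise r^2 — genotype
(composite) correlation by default, since real data are unphased; an EM
haplotype-frequency estimator is available. The refined region is the
positional envelope of SNPs with r^2 > 0.4, always containing the lead;
the envelope (rather than a contiguous run) matches how such refinements
are reported as single intervals. When no region holds a genome-wide
significant SNP the pipeline refines the scan's candidate regions
instead, each led by its most associated SNP, and records that the
refinement is exploratory.

**CNV screen.** Normalized copy numbers are rounded half-up to
half-integer classes (1 = diploid normal; above 2.25 pools into a
multicopy class). CNVRs pass quality control if the 1-D silhouette of the
class clustering exceeds 0.7 and the combined frequency of non-modal
classes exceeds 0.05. The screened statistic is the carrier (non-diploid)
frequency contrast between first and last cohorts. Because the emulated
study's printed |RFD| cutoff of 4.1 exceeds any bound a plain frequency
difference can reach, the default RFD is the pooled-SE z-score form
(fB − fA)/sqrt(fbar(1−fbar)(1/nA+1/nB)), which naturally reaches such
values; a bounded relative form 2(fB−fA)/(fB+fA) is selectable. Either
way the screen itself is formula-agnostic: CNVRs at or above the
empirical top-5% |RFD| quantile are selected (ties at the cutoff kept).
Variance explained regresses the phenotype on the class, linearly coded
by default.

## Numerical choices and degenerate inputs

* Internal interval coordinates are 0-based half-open; VCF (1-based) and
  BED dialects are converted at the boundary only. A 1-based site p lies
  in [start, end) iff start <= p−1 < end.
* Empirical thresholds use type-7 (linear interpolation) quantiles, and
  warn below 100/tail values.
* Monomorphic sites: flagged uninformative by the Fst components (0, 0),
  dropped before PCA scaling, flagged missing by the association scan,
  undefined for r^2.
* The identical-cohorts Fst is <= 0, not exactly 0: the unbiased
  estimator centres undifferentiated sites at zero only in expectation.
* dAF bin assignment adds a 1e-9 guard before flooring so that values
  computed as 0.05 land in bin 2 regardless of floating-point residue.
* EHH walks stop at the first value below the cutoff; integration keeps
  points at or above it. Ties for the lead SNP break to the smaller
  coordinate; screening ties at the |RFD| cutoff are kept.
* All randomness flows from one seed; the pipeline derives per-stage
  sub-seeds, so runs are bit-identical under a fixed seed.

## What the tests show — and what they cannot

The test suite establishes, on simulated data: exactness of every core
statistic against independently coded brute-force oracles (Weir-Cockerham
components, EHH/iHH integration, nucleotide diversity, haplotype r^2,
dense-GLS equivalence of the spectral mixed model); calibration (null
association scans are uniform with genomic control in [0.9, 1.1]; neutral
drift variance matches p(1−p)/2Ne at Ne = 4NmNf/(Nm+Nf); the CNV screen's
false-positive rate equals its nominal tail); and directional properties
of selection (causal frequency shifts exceed neutral ones, diversity
falls, LD to lead SNPs grows across generations).

The generator does not emulate: sequencing depth or genotyping error
(depth filters are exercised on crafted tables only), unphased real data
for the haplotype statistics (the pipeline refuses to pseudo-phase),
overlapping generations, pedigree-based inbreeding avoidance, mutation
(standing variation dominates over ten generations), or genome-scale SNP
counts. Consequently a passing suite says the estimators are correct and
calibrated, not that the pipeline's power on a real 8-million-SNP,
119-sample dataset matches the emulated study's.

## Known limitations

Two scale effects are worth stating plainly, since they were measured
during development. First, XP-EHH carries little localizing information
at this design's scale: with 60 haplotypes per cohort, ten transmissions,
and selection on standing variants shared through a common ancestral
pool, the query cohort's iHH is dominated by genome-wide drift
homogenization (pairwise IBD ~ 4.7%, sitting at the 0.05 EHH cutoff), so
the joint Fst x XP-EHH intersection is far sparser than at genome scale
— the Fst component does nearly all the work. Second, at n = 119 with a
ten-locus h2 = 0.3 architecture, single-SNP associations rarely clear a
Bonferroni cutoff; the emulated study's genome-wide hits rode a
between-generation trend several times larger, relative to
within-generation variation, than a ten-locus additive model can sustain.
Both behaviours are properties of the scaled design, not of the
estimators, and both are visible in the acceptance suite's
parameter-recovery study.

## Problem sizes used by the tests and scripts

Module tests run on toy fixtures and scaled simulations (populations of
120-750, 150-600 SNPs). The acceptance suite uses the full default
configuration (750 x 10 generations, 3 x 5 Mb, 3,000 SNPs) for its
20-replicate parameter-recovery study and its determinism check, about
17 s per replicate; `scripts/acceptance.R` performs one full default run.
The numbered scripts under `analysis/` re-run the same workflow
stage-by-stage from persisted intermediates.
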