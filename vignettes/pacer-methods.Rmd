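---
title: "Passenger-clock estimation of mCA clonal expansion rates: model, generator design, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passenger-clock estimation of mCA clonal expansion rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacermca)
```

## The method

A hematopoietic stem cell lineage accumulates neutral clock-like
substitutions (pyrimidine-normalized C>T and T>C) at an approximately
constant rate. When one cell in that lineage acquires an mCA driver and
expands, every passenger already present in the founding cell
("ancestral" passengers) rises to the clone's cell fraction and becomes
detectable in bulk WGS; passengers acquired after the driver stay
private to sub-lineages and mostly remain below the detection limit.
The detectable passenger burden therefore measures the *age of the
driver*: at matched calendar age and clone size, a larger burden means
a later driver, hence a faster expansion.

The estimator is:

1. **Count** clock-like somatic singletons per individual, keeping
   variants with depth in [25, 100], VAF at most 0.35 (higher VAF is
   presumed germline), and no CHIP driver-gene annotation.
2. **Adjust**: fit an NB2 negative binomial regression of the count on
   age at draw, sex, clonal fraction, and study indicators (log link).
3. **Normalize**: take raw residuals, apply a Yeo-Johnson transform
   with the power chosen by profile maximum likelihood, and z-score.
   The result — the PACER score — is standard-normal-scale, rank-
   identical to the residuals.
4. **Aggregate**: per-mCA fitness is the median score over carriers of
   a lesion, keyed by (chromosome, arm, copy type), with fold change
   reported against mosaic X loss.

Assumptions worth stating: the passenger clock rate is homogeneous
across individuals up to modest overdispersion; the covariates capture
detectability differences linearly on the log scale; and residual rank,
not magnitude, carries the biological signal (which is why the choice
among raw / Pearson / deviance residuals — all offered — only reorders
spacing, never ranks, after the monotone transform).

## Tunable parameters

Scoring side:

* `covariates` (default age, sex, clonal fraction, study) — study
  indicators are dropped automatically when only one study is present.
* `residual_type` — `"raw"` (default), `"pearson"`, `"deviance"`.
* `transform` — `"yeo_johnson"` (default) or `"rank_int"` (Blom
  rank-based inverse normal, the convention used for the genotype
  association scan, which transforms counts directly).
* Filter thresholds follow their printed definitions as strict
  inequalities: BAF autocorrelation > 0.05 excludes; lod_baf_phase
  below 20 (autosomal) / 5 (sex chromosomes) excludes; duplication
  windows 2–10 Mb (coverage > 2.25) and 50–250 Mb (> 2.5) exclude;
  relative coverage < 0.5 excludes; minimum size 2 Mb. Boundary values
  pass. Segments of 10–50 Mb face no duplication-coverage rule because
  no rule is defined there.
* Depth 25 and 100 and VAF 0.35 pass the variant filter (the stated
  exclusions are "below 25", "above 100", "exceeding 35%").

Generator side (defaults in `sim_config()`), with units and rationale:

* `passenger_rate_mu = 2` detectable clock-like passengers per year of
  pre-driver lineage. HSC genomes gain roughly 15–20 substitutions per
  year, about two-thirds clock-like, of which a sixth or so are
  callable as somatic singletons at 38x — order 1–3 per year.
* `overdispersion_k = 10` (Gamma–Poisson shape). The somatic clock is
  empirically tight; k = 10 adds mild extra-Poisson noise. `Inf` gives
  the Poisson limit; `misspec_frailty = TRUE` switches to a lognormal
  frailty for robustness checks of the NB specification.
* `n_hsc = 1e4` median effective stem-cell pool, the lower end of
  published effective-size estimates, chosen so clones across
  s = 0.1–0.3/yr reach the detection limit within a human lifespan.
* `n_hsc_sd_log = 0.75`: per-individual lognormal variation of the
  pool, reflecting the order-of-magnitude spread in effective HSC
  numbers across people. This also prevents the observed clonal
  fraction from being a deterministic function of (s, driver age) — a
  degeneracy under which the clonal-fraction covariate would absorb
  the very fitness differences the score estimates.
* `fitness_sd_log = 0.3`: within-lesion fitness variability, matching
  the observation that carriers of the same mCA expand at very
  different rates.
* `detection_limit_cf = 0.05`; the `wgs_38x` preset (0.09) encodes the
  8–10% clonal-fraction SNV detectability of 38x WGS.
* `mca_types`: five lesions at s = 0.10 (X loss), 0.15 (chr12 gain),
  0.20 (9p CN-LOH), 0.25 (20q loss), 0.30 (11q CN-LOH). X loss gets
  the largest prevalence weight (0.30), as in real female cohorts,
  which also stabilizes the fold-change reference group. 9p CN-LOH is
  deliberately mid-range: see "Limitations" below.
* Germline modifier SNP at allele frequency 0.21 with multiplicative
  per-allele effect on s (presets none / −0.15 / −0.35 "strong"), plus
  a non-causal partner SNP at LD r² ≈ 0.8 for conditional analyses.
* Erythrocyte–fitness coupling for chr9p clones (presets 0 / 2 / 8
  ×10¹² cells/L per unit s). The "strong" preset was calibrated by
  power analysis during design so that the chr9p erythrocyte
  regression detects the coupling with ~85–90% power at ~60–70
  carriers, the scale of the package's validation studies.

## What the generator emulates, and what it does not

Emulated: logistic clone growth to a finite stem-cell pool; uniform
driver acquisition over life; Gamma–Poisson ancestral passenger counts;
depth-Poisson / VAF-binomial observation at 38x; contaminating
non-clock-like somatic variants, germline heterozygous leaks near VAF
0.5, CHIP-gene-annotated rows (so the filters face real false
positives); QC failures (BAF autocorrelation, sex discordance, low
lod_baf_phase); CHIP carriers and multi-mCA individuals for the cohort
exclusions; blood counts with a fitness-coupled erythrocyte channel for
9p clones.

Not emulated: kinship or population structure (the association scan is
fixed-effects OLS on unrelated individuals — the desk-scale analogue of
a kinship-adjusted mixed model); LD beyond the single engineered
modifier/partner pair; ancestry principal components (accepted as
covariate columns if supplied, never computed); read-level sequencing
artifacts; CN-LOH duplication of passenger VAF (passenger VAF is kept
at cf/2 everywhere; under CN-LOH, passengers on the duplicated
haplotype could rise to ≈ cf, which would only strengthen the
VAF-filter effects discussed below); serial samples; death or
progression (no survivor bias). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated clonal
dynamics, not robustness to every real-data pathology.

## Numerical choices

* NB2 fit by maximum likelihood (glm.nb engine), log link,
  convergence tolerance 1e-8, up to 200 iterations; convergence
  diagnostics and captured warnings are carried on the fit object, and
  a non-converged fit warns rather than failing silently. Constant
  covariates are dropped (an all-constant design reduces to the
  intercept-only fit, whose fitted mean equals the sample mean);
  genuinely collinear designs are an error.
* Yeo-Johnson power estimated by profile likelihood over
  lambda ∈ [−3, 5] with `optimize()` (tolerance 1e-7); the transform
  is strictly monotone for every lambda, so ranks are preserved
  exactly. A constant residual vector is a "degenerate residuals"
  error.
* Rank-based inverse normal uses Blom offsets,
  qnorm((rank − 3/8)/(n + 1/4)), with average ranks for ties.
* The mCA-chromosome density test compares each individual's
  mCA-chromosome passenger count against a Binomial(total, length
  share) null, and aggregates across individuals with a
  length-standardized z statistic; per-sample exact binomial p-values
  are also returned.
* Coordinates are 1-based inclusive; size_mb = (end − start + 1)/1e6.
  Arm assignment uses bundled approximate GRCh38 centromere midpoints;
  a segment spanning the centromere is "whole".
* Ratio-of-medians fold changes on a z-score scale can be negative or
  explode near zero; the table computes them as defined but carries a
  machine-readable `sign_warning` and always includes the stable
  difference-of-medians column.
* The curated lymphoid and myeloid mCA sets share one entry (9q
  CN-LOH); `classify_mca()` resolves it by explicit argument
  (first-listed "lymphoid" by default, or "myeloid"/"both").
* "More than 25 individuals" for the external-fitness comparison is
  strict (n > 25).

## Design decisions that were genuinely open

* **Residual type**: the scoring description says only "residuals"; raw
  residuals are the default because the monotone transform makes the
  choice rank-irrelevant, and switches expose the alternatives.
* **Study covariate**: included in the scoring model whenever more than
  one study is present (the fuller of the two covariate sets described
  for the method), and droppable via `covariates`.
* **Inverse-normal reading**: the scoring path applies
  Yeo-Johnson-then-z-score (the named transform); the genotype scan
  applies rank-based inverse normal to the counts themselves — each
  analysis uses its own stated convention.
* **Driver-time prior**: uniform over (0, age); configurable. Combined
  with logistic growth this intentionally produces a realistic mix of
  rare, detectable, and saturated clones.
* **Detection limit exactly 1** is allowed as a degenerate setting (no
  clone observable) so the empty-cohort contract is testable.

## Known limitations

* **Saturated clones are uninformative.** Once a clone approaches
  fixation (cf → 1), its passengers sit near VAF 0.5 and the ≤ 0.35
  germline filter removes almost all of them: counts collapse to near
  zero regardless of driver age, and no covariate adjustment can
  recover the clock. This is a genuine identifiability limit of
  passenger clocks, not an implementation artifact. It is why the
  generator's 9p CN-LOH — the lesion used for the erythrocyte power
  study — is assigned a mid-range fitness whose clones populate the
  informative clonal-fraction range, and why the highest-fitness
  simulated groups separate only modestly in median score.
* **Score normality is approximate under the default conditions.** The
  VAF-thinned counts have a discrete mass at small values that a
  monotone transform cannot spread; scores pass a strict
  Kolmogorov–Smirnov normality check when counts are drawn from a
  well-specified NB model, but not under heavy thinning. Mean-0 / SD-1
  standardization and rank preservation hold regardless.
* **Fold changes vs X loss are sign-unstable** whenever the reference
  median is near or below zero; prefer `fitness_diff`.
* The association stage is a fixed-effects stand-in: no kinship, no
  rare-variant omnibus tests, no external LD reference.

## Problem sizes used in the test suite

Validation cohorts are simulated at 400–6,200 candidate individuals
(the reference validation cohort scores ≈ 2,000 after retention, QC and
cohort exclusion); calibration uses 1,000 null SNPs; seed-replication
loops use 10–20 seeds; the brute-force NB likelihood oracle runs at
n = 30 over a 9×9×9×15 parameter grid. All suite randomness is under
fixed seeds.
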