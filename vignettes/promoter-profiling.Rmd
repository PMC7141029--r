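---
title: "Promoter coverage profiling of cfDNA: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter coverage profiling of cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpromoter)
```

## The biological model

Plasma cell-free DNA (cfDNA) is released by apoptotic cells after
nucleases digest the exposed linker DNA between nucleosomes; DNA that was
nucleosome-bound survives and circulates. cfDNA coverage therefore carries
a *nucleosome footprint* of its tissues of origin: promoters of
transcriptionally active genes are nucleosome-depleted in the source
tissue, the naked DNA is digested, and their primary transcription start
site region (pTSS, the window from -1 kb to +1 kb around the TSS) shows
*depleted* sequencing coverage. Read depth at the pTSS is thus an inverse
proxy for gene expression.

In pregnancy, cfDNA is a two-tissue mixture: roughly 10% derives from
placental trophoblasts and the rest mostly from maternal hematopoietic
cells. Placenta-origin complications (macrosomia, fetal growth
restriction, gestational diabetes, preeclampsia) perturb expression in
those tissues, so promoter coverage profiles measured early in gestation
can be mined for predictive biomarkers. `cfpromoter` implements that
analysis end to end:

1. **Annotation** — strand-aware pTSS windows from refFlat/BED12
   transcript models (`build_ptss_windows()`); TSS = `txStart` on the plus
   strand, `txEnd` on the minus strand, coordinates 0-based half-open
   throughout.
2. **Coverage** — fragments counted per window with a >= 1 bp overlap
   rule, normalized to RPKM = count x 1e9 / (window length x total mapped
   fragments); per-base depth feeds TSS metagene profiles
   (`build_coverage_matrix()`, `metagene_profile()`).
3. **Differential coverage** — per-promoter two-sided Wilcoxon rank-sum
   test between cases and controls, Benjamini-Hochberg FDR, selection at
   FDR <= 0.1 and |log2 fold change| >= 1 (`select_differential()`).
4. **Classification** — per-promoter discretization at the balanced-
   accuracy-optimal cutoff, strict `value > cutoff` binarization,
   bidirectional AIC stepwise logistic selection, leave-one-out
   cross-validation, and ROC evaluation with DeLong confidence intervals
   (`run_training()`, `roc_analysis()`).
5. **Prediction** — `predict()` computes the logit
   `beta0 + sum(beta_i x_i)`; `published_ma_classifier()` ships the
   12-gene macrosomia model whose intercept is 2.180.

## The synthetic cohort generator

Real inputs (patient WGS, microarray expression panels) cannot ship with
the package, so a first-class simulator generates every input the
pipeline consumes:

* `simulate_gene_universe()` builds a miniature genome with TSSs >= 10 kb
  apart (promoter windows never overlap), log-normal expression for
  placenta and whole blood with a shared gene-level component
  (cross-tissue correlation ~0.6), tissue-specific genes (~8% per
  tissue), unexpressed genes (~10%), and the top500/bottom500 rank sets.
* `occupancy_model()` turns expression into promoter *activity* (the
  within-tissue expression percentile; 0 for unexpressed genes). The
  fragment-start intensity dips at each TSS by
  `activity x depletion_depth x exp(-d^2 / (2 sigma^2))` with
  `sigma = depletion_width / 2` (default width 1000 bp), so a fully
  active promoter at `depletion_depth = 0.6` loses 60% of its fragment
  starts at the TSS and essentially nothing 1 kb away. The Gaussian shape
  is a deliberate, parameter-sparse stand-in for real nucleosome
  phasing, which is only qualitatively constrained.
* `simulate_sample_fragments()` samples fragments by thinning a uniform
  genome-wide intensity with the mixture
  `placental_fraction x placenta + (1 - placental_fraction) x blood`
  (default placental fraction 0.10). Fragment lengths are
  Normal(167, 20) bp truncated to [50, 400] — 167 bp is the canonical
  mononucleosome cfDNA mode.
* `simulate_cohort()` plants case-specific signal: inside each planted
  pTSS window the case fragment-start intensity is multiplied by
  `2^effect_lfc`, so the expected case/control window-count ratio matches
  the target log2 fold change directly. (Routing the planted effect
  through the activity channel cannot reach |log2FC| = 1.5: with a 10%
  placental fraction the mixture caps activity-driven coverage shifts at
  a few percent.) Fragment-length smearing across window edges shrinks
  the realized log2FC slightly (about 1.4 at a target of 1.5). BMI is
  Normal(22.5, 2.5) with a +1.5 kg/m^2 case shift by default;
  gestational age Normal(17, 1.5) weeks. One master seed; sample `i`
  uses `seed + 1000 + i`, so cohorts are reproducible sample by sample.

### What the simulator does and does not emulate

It reproduces the features the pipeline's statistics rely on: promoter
dips proportional to expression, the two-tissue mixture, library-size
variation handled by RPKM, count noise at low coverage, and planted
differential promoters with known truth. It does **not** model GC or
mappability bias, sequencing error, fragment-size differences between
fetal and maternal DNA, copy-number changes, batch effects between
sequencing platforms, or correlated biological variation between
promoters. Green tests therefore demonstrate correctness of the
*methods* under the stated generative model, not clinical performance on
patient data; the published cohort AUCs (0.766-0.813) require patient
sequencing data and are treated as context only.

## Numerical and design choices

* **Counting rule** — a fragment increments every window it overlaps by
  >= 1 bp (half-open arithmetic: abutting intervals do not overlap).
  Window *counts* feed RPKM; per-base depth is used only for metagene
  profiles.
* **Metagene baseline** — profiles are normalized by the mean depth over
  the outermost 10% of positions on each side of the window; the
  published figures use an unspecified relative normalization, and a
  pinned baseline makes the central/flank ratio testable. Minus-strand
  windows are reversed so positive offsets are always downstream.
* **Pseudocount** — 0.01 RPKM is added to both group means in the log2
  fold change, keeping sign and ordering stable when a group mean is 0.
* **Wilcoxon p** — exact enumeration (via the null rank-sum distribution)
  when the pooled sample is <= 20 with no ties; otherwise the normal
  approximation with tie and continuity corrections. At 10 vs 10 with
  tied low counts the corrected p is mildly conservative; the distortion
  vanishes by 40 vs 40 (the package's null-calibration tests run there).
* **Cutpoint search** — candidates are midpoints between consecutive
  sorted unique values plus one candidate below the minimum and one
  above the maximum; scoring is direction-agnostic
  (`max(BA, 1 - BA)`) because the logistic coefficient sign absorbs the
  orientation; ties go to the smallest candidate. Binarization is strict:
  a value equal to the cutoff maps to 0.
* **Stepwise scope** — bidirectional from the intercept-only model under
  AIC (it matches `stats::step()` move for move), with a `max_features`
  cap (default 15; the published classifiers carry 10-13 genes). Ties
  between moves are broken by candidate order, so selection is
  deterministic. AIC admits a handful of noise features at realistic
  sample sizes — that is a property of AIC itself, and the honest
  cross-validation below is the guard against trusting training fit.
* **Separation** — complete separation is flagged and coefficients are
  rescaled so the largest |beta| is 15; rescaling (rather than
  per-coordinate clamping) preserves which side of the boundary every
  sample is on.
* **LOOCV scope** — by default the feature subset and the discretization
  cutoffs are frozen from the full training cohort and only coefficients
  are refit per fold. This mirrors fixed published gene sets but is
  optimistically biased; `loocv_mode = "strict"` re-runs the entire path
  (differential screening, gene reduction, cutoffs, stepwise) inside
  every fold and is the mode used for null-calibration checks.
* **Gene-level features** — when several transcripts of a gene survive
  discovery, the transcript with the smallest discovery p represents the
  gene (deterministic; the published equation is gene-keyed).
* **Probability threshold** — chosen on the LOOCV probabilities by
  maximizing balanced accuracy, smallest maximizer on ties. The ROC
  operating threshold uses the same rule.
* **BMI** — enters as a raw continuous covariate appended to the binary
  design; no cutoff is published for it.
* **Degenerate inputs** — zero-variance promoters are dropped from
  z-scoring (emitted as zeros) and from logistic designs with warnings;
  single-class folds fall back to the full fit with a warning; empty
  gene sets, missing metadata, and training/validation sample overlap
  are errors, not silent behavior.

## Problem sizes used by the test-suite cohorts

Simulated cohorts are sized like the study design while staying desk-
scale: 2000 promoters with 40 cases + 40 controls and 50 planted
promoters at log2FC 1.5 for differential-recovery and classifier checks
(~0.5x mean genome coverage, i.e. ~75k fragments per sample on the 25 Mb
miniature genome; ~0.003 fragment starts per bp); 1000 promoters with 20
healthy samples at ~1x coverage for the metagene mechanism checks, where
per-base profiles need the extra depth; and ten 40 + 40 null cohorts for
calibration. Discovery uses the first 10 cases and 10 controls of the
training cohort, matching the 10 vs 10 discovery design.

## A compact end-to-end run

```{r example, eval = FALSE}
u   <- simulate_gene_universe(1000, n_chromosomes = 2, seed = 1)
occ <- occupancy_model(u, depletion_depth = 0.6)
sp  <- cohort_spec(20, 20,
                   planted_promoters = u$transcripts$transcript_id[1:20],
                   effect_lfc = 1.5, seed = 1)
co  <- simulate_cohort(u, occ, sp)
w   <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
cov <- build_coverage_matrix(co$fragments, w, co$metadata)

diff  <- run_discovery(cov, windows = w, n_per_group = 10)
train <- run_training(cov, diff)
glance(train$roc)
tidy(train$classifier)

# frozen model on an independent cohort
sp2 <- sp; sp2$seed <- 99L
co2 <- simulate_cohort(u, occ, sp2)
co2$metadata$sample_id <- paste0("V", co2$metadata$sample_id)
names(co2$fragments) <- co2$metadata$sample_id
cov2 <- build_coverage_matrix(co2$fragments, w, co2$metadata)
glance(run_validation(cov2, train$classifier))
```

## Known limitations

* The fixed-subset LOOCV (the default, matching fixed published gene
  sets) overstates out-of-sample performance; use strict mode for honest
  error estimates.
* RPKM corrects library size only; no GC, mappability, or batch
  correction is applied (none was in the source analysis).
* The published macrosomia classifier ships with coefficients only; its
  per-gene cutoffs and probability threshold were published in
  supplementary tables that are not reproduced, so scoring raw coverages
  with it requires user-supplied cutoffs (already-discretized input
  works out of the box).
* Transcript TSSs are taken from `txStart`/`txEnd`; no curated TSS set
  or alternative-promoter inference is used.
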