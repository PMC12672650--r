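---
title: "Dynamic organellar maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic organellar maps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doms)
```

This vignette documents the statistical models behind `doms`, the
parameters a user may want to change, the assumptions of the synthetic
fractionation simulator, and the places where the design was genuinely
open and a choice had to be made.

## The measurement model

Differential centrifugation distributes each protein over six pellets
(1k, 3k, 6k, 12k, 24k, 78k × g) and a final supernatant (the cytosol
fraction). Label-free MS intensities per fraction are assumed
proportional to the protein's amount in that fraction divided by the
fraction's total protein content, because equal protein amounts are
loaded per MS run; the per-fraction BCA yield restores absolute
proportions where needed (the 7-point pool profiles). The six-fraction
**normalized profile** — intensities divided by their sum — is the unit
of all mapping analyses. Its key property is that it is invariant to
protein abundance and depends only on subcellular distribution.

Assumptions worth stating explicitly:

* profiles of one compartment are homogeneous up to multiplicative
  replicate noise;
* a protein distributed over two compartments has a profile that is the
  amount-weighted mixture of the two compartment profiles (linearity of
  MS intensity);
* missing values arise from left-censoring at the detection limit, not
  at random.

## Movement–reproducibility analysis

Delta profiles (treatment − control, replicate-paired by index, the
only pairing consistent with cognate replicates) live in the rank-5
subspace `{x ∈ R⁶ : Σx = 0}`. The outlier test proceeds per replicate:

1. project deltas onto an orthonormal basis of the sum-zero subspace;
2. whiten each protein's delta by its profile-implied noise covariance
   (see below);
3. estimate location and scatter from the least-moving 75% of proteins,
   re-trimming iteratively for 11 rounds (the static data proportion
   and iteration count are the test's two tunables);
4. rescale the trimmed covariance by the normal-model consistency
   factor `α / P(χ²₇ ≤ χ²₅,α)` with α = 0.75, and refer squared robust
   Mahalanobis distances to χ²₅.

**Why the per-protein whitening (step 2).** Under multiplicative noise
with common coefficient of variation σ, a protein with mean normalized
profile p has delta covariance proportional to
`P(I − 1pᵀ)(I − p1ᵀ)P` with `P = diag(p)` — known up to the single
scale σ². Profiles differ strongly between compartments (a ribosomal
protein concentrates 70% of its signal in one fraction; a cytosolic
protein spreads evenly), so the *scale and shape* of null deltas is
compartment-dependent. A pooled covariance alone therefore produces
compartment-biased p-values: conservative for concentrated profiles,
anticonservative for spread ones. Whitening by the profile-implied
covariance puts all proteins on one scale before the pooled robust
estimate; the package's tests verify that null p-values are then
uniform (Kolmogorov–Smirnov distance ≈ 0.02 at n = 2000). The trimming
step still protects the scatter estimate from the very relocalizers
the test is meant to find.

Replicate p-values are Fisher-combined (−2Σlog p ~ χ²₂ₖ), BH-adjusted
across the tested universe (per comparison: DTT and tunicamycin
separately), and −log10-transformed into M. R is the median of the
three pairwise Pearson correlations of replicate deltas; a constant
delta has undefined correlation and the protein is flagged and never a
hit. Degenerate inputs are handled explicitly: p = 0 is clamped to the
smallest positive double with a warning, singular scatter matrices are
ridge-regularized with a warning.

## Classification

The SVM layer uses `e1071` (libsvm) with an RBF kernel and pairwise-
coupling probability outputs; scores are renormalized to sum exactly
to 1. Hyperparameters are drawn uniformly for C over [1, 30] and
log-uniformly for γ over [1, 50] (five candidates, stratified
five-fold cross-validated accuracy); log-uniform sampling for γ is a
choice — the search range spans almost two decades and a scale
parameter is naturally sampled on the log scale. Ties in the score
argmax are broken lexicographically and flagged.

The iterative marker refinement trains on the current set, classifies
every profiled protein, keeps correctly recalled markers, and adds
non-markers whose at-least-medium-confidence prediction matches the
reference annotation, stopping at 100% recall with no additions. The
training seed is held fixed across rounds so that the converged state
is a fixed point: rerunning the loop on its own output terminates in
one round without changes. Initial sets mirror common practice: the
100 most abundant reference proteins per large class, everything for
small classes. Classes with fewer than five markers are excluded from
training with a warning; lipid droplets and peroxisomes are excluded
from benchmarking because their test splits are uninformative.

## Pools, organelle shifts, ER screen

Pool profiles weight the 7 fraction intensities by per-condition mean
relative yields and renormalize; the 7th entry is the cytosolic pool
and the first six sum to the non-cytosolic pool (a partition of
recovery, asserted in tests). The pool shift test needs a measured
pool in all replicates of at least one treatment; the hit filter is
FDR < 5% plus per-treatment significance (0.05 / 0.1), an absolute
change above 10 percentage points under both treatments, and sign
agreement. Positive changes point toward the cytosol.

The organelle shift test multiplies the smallest of six datapoint-wise
paired-t p-values by six, capped at 1. That arithmetic is a min-p
Bonferroni-style correction and is implemented exactly as such; the
shift magnitude is the mean L1 distance between cognate replicate
averages, binned at 0.1/0.2/0.3 (0.1 approximates typical
inter-replicate scatter).

The ER screen correlates each protein's condition-average 6-point
profile with the average ER marker profile. Averaging over replicates
is the minimal reading of "the" profile per condition and suppresses
noise attenuation in the correlation; concatenated 18-point profiles
would weight replicate noise three times instead. Candidates must be
MR hits with positive ΔcorrelER, stress correlation > 0.75 and a
post-ER secretory localization (signal peptide and/or transmembrane
domain, no mitochondrial transit peptide, localized to ERGIC, Golgi,
plasma membrane, cell wall, vacuole or endosomes). Proteins failing
only the positive-ΔcorrelER filter are reported as near misses rather
than rescued automatically — borderline rescues are a judgment call
that belongs to the analyst, not the tool.

## Abundance statistics

Left-censored missing values are imputed per sample from
`Normal(mean − 1.8·sd, (0.3·sd)²)` of the observed values. The volcano
analysis uses a pooled-variance t-test (the conventional default for
3-vs-3 label-free comparisons) plus the S0-modified statistic
`t' = Δmean/(SE + s0)` with s0 = 0.1. Significance is a threshold on
|t'| calibrated by group-label permutation: the estimated FDR at
cut-off c is the median permuted exceedance count over the observed
count, and the smallest c with FDR ≤ 5% defines the hits. At n = 3+3
all 20 balanced relabelings are enumerated (including the identity,
which makes the estimate slightly conservative); larger designs use
250 random relabelings.

The proteomic ruler anchors total protein mass to DNA mass via histone
intensity; the histone set is a named argument because any anchoring
set of DNA-proportional proteins works. The base-pair molar mass is
fixed at 650 g/mol. The interpolated protein concentration reports a
truncated integer (83 from 83.5) — truncation, not rounding, is the
convention that makes the printed anchor values self-consistent.

## What the simulator emulates — and what it does not

`simulate_experiment` generates: compartment-specific 6-fraction
profiles (12 templates with pairwise L1 distance ≥ 0.4, heavy
organelles sedimenting early, ribosomes in the 78k pellet), cytosol
leakage per compartment, per-protein abundances log-uniform over four
decades, multiplicative log-normal replicate noise (CV 10% by
default), left-censoring below a detection threshold, Poisson MS/MS
counts proportional to log-intensity, planted relocalizations as
template mixtures `(1−α)·A + α·B`, planted abundance changes, and a
full-proteome sample per map. Template shapes were chosen to mimic the
qualitative geometry of real maps: membrane organelles overlap
substantially across the mid pellets, so that a protein whose profile
is dominated (α ≥ 0.7) by ER character correlates strongly (> 0.8
noiseless) with the ER average — as real ER-retained cargo does —
while the 12 classes remain separable. Per-protein RNG streams are
derived from the global seed by an integer hash, so outputs are stable
under protein reordering.

Not emulated: peptide-level effects and shared peptides,
match-between-runs artifacts, fraction-to-fraction noise correlation
(independence per fraction is assumed), compositional coupling between
proteins, and annotation errors in the reference. Passing tests on
simulated data therefore demonstrate the correctness and calibration
of the statistical machinery under the stated noise model — not
performance on real spectra, where noise is heavier-tailed and
profiles less homogeneous.

## Problem sizes and numerical conventions

The test-suite and acceptance experiments use 2000-protein maps for
null calibration and MR recovery, 1500 for the ER screen, and 2400 for
marker training (so that the initial top-100-per-class selection is a
proper subset and the refinement loop has room to grow), with three
replicates per condition throughout — comfortably sized for the
statistics while keeping a full run in the order of a minute.
Normalization requires at least one positive intensity and errors on
all-zero profiles; sum-to-1 is enforced to 1e-9; probability scores to
1e-6. PCA errors only on fully degenerate (rank-0) input: perfectly
collinear profiles are legal and yield zero PC2 variance.

## Known limitations

* The robust outlier test's whitening is first-order in the noise CV;
  at CVs well above ~20% the χ²₅ reference degrades.
* The SVM probability calibration (libsvm's internal CV) is treated as
  a black box; only the scores' ordering and normalization are
  guaranteed, which is all the confidence tiers require.
* The pool shift test requires two treatments; single-treatment
  designs fall back to the MR machinery only.
* Hit counts on real deposited data are not reproduced here; they
  depend on the measured proteomes. The package reproduces the
  *method*, validated by planted-truth recovery.
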