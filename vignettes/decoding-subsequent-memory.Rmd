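---
title: "Decoding subsequent memory from simulated BOLD data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding subsequent memory from simulated BOLD data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submvpa)
```

## The problem

In a subsequent-memory fMRI design, brain activity recorded while a
participant encodes each item is sorted afterwards by whether that item was
later remembered or forgotten. Multivoxel pattern analysis (MVPA) asks
whether the *joint* activity pattern over many voxels at encoding time
predicts the later mnemonic outcome, trial by trial. `submvpa` implements
this analysis end to end for a specific paradigm — fast-mapping (FM) versus
explicit-encoding (EE) associative learning, with recognition tested by
4-alternative forced choice (4AFC) outside the scanner — together with a
synthetic BOLD generator so that every stage can be exercised, tested and
calibrated without access to real scans.

The pipeline is:

1. **Paradigm** — generate the trial schedule: 124 events per subject in 3
   runs (40/40/44 events), each event a fixed train of question (3 s),
   picture (2 s), response (1.5 s) and feedback (0.5 s) stages followed by
   a 2 s or 6 s fixation, so events last 9 or 13 s (mean 11 s). Runs open
   with a 12 s lead-in and a 6 s blank follows each 8-event sequence.
2. **Simulation** — 4D BOLD runs at TR = 2 s: baseline + AR(1) noise +
   slow drift, plus a class-dependent multivoxel pattern inside designated
   regions on novel-target trials, convolved with a double-gamma
   hemodynamic response function (HRF).
3. **Preprocessing** — per-voxel detrending; z-scoring against volumes
   acquired during the peak window of baseline trials; averaging the
   volumes 6–8 s post stimulus onset into one feature vector per trial;
   random down-sampling of the majority class per run (counterbalancing)
   so chance is 0.5.
4. **Decoding** — linear soft-margin SVM on the 100 voxels with the
   largest two-group ANOVA F, with selection recomputed inside every
   training fold; leave-one-run-out (within subject) and
   leave-one-subject-out (cross subject) cross-validation; confusion-matrix
   metrics with *remembered* as the positive class.
5. **Inference** — dataset-wise label permutation; region-restricted
   (ROI) decoding; spherical searchlight mapping with per-center binomial
   above-chance thresholding.

## The design arithmetic

The schedule generator treats the printed run durations as authoritative.
With 40 events averaging 11 s, a 12 s lead-in and five 6 s blanks, runs 1–2
last $12 + 40 \times 11 + 5 \times 6 = 482$ s; run 3, with an extra
4-event sequence and a sixth blank, lasts $12 + 44 \times 11 + 6 \times 6
= 532$ s. At TR = 2 s this yields 241/241/266 volumes. This forces one
reading of the sequence-blank rule: the 6 s blank follows *every*
sequence, including the last of each run — no other placement reproduces
both durations. It also forces the fixation balance (half 2 s, half 6 s)
to hold at *run* level; the generator enforces exactly that and leaves
within-sequence composition a uniform shuffle, since the printed
arithmetic requires nothing stronger.

```{r design}
d <- make_subject_design("FM", seed = 1)
vapply(d$runs, `[[`, 0, "total_duration")
design_trial_counts(d)
```

## The simulation model

Each voxel's time series is

$$y_v(t) = \mu + \varepsilon_v(t) + d_v(t) + s_v(t),$$

where $\varepsilon_v$ is AR(1) noise (innovation SD $\sigma$, coefficient
$\rho$), $d_v$ is a per-voxel random mix of a linear ramp and a half-cycle
cosine (slow drift), and the signal $s_v$ is nonzero only inside
informative regions: a fixed pattern vector per class (drawn once per
subject per region from a standard normal) scaled by
`effect_size` $\times$ the *marginal* noise SD
$\sigma/\sqrt{1-\rho^2}$, and modulated by a 3.5 s boxcar (picture +
response window) convolved with the HRF. The HRF is the canonical
double-gamma difference `dgamma(t, 6, 1) - dgamma(t, 16, 1)/6` (peak
$\approx 5$ s, late undershoot), normalized so a single event's peak
response is 1; the paradigm fits no GLM, so only the 6–8 s peak-window
convention constrains this choice.

Key generator parameters and their defaults:

| parameter | default | meaning |
|---|---|---|
| `grid_dim` | 16 × 16 × 8 | voxel grid; a desk-scale stand-in for the 64 × 64 × 32 acquisition |
| `TR` | 2 s | volume sampling interval |
| `voxel_size` | 3 × 3 × 5 mm | voxel geometry (used for world coordinates) |
| `effect_size` | 1 | per-event peak pattern amplitude in marginal-noise-SD units; **illustrative, not fitted** — no effect-size estimate exists for the real signal |
| `noise_sd`, `ar1_coef` | 1, 0.3 | AR(1) innovation SD and lag-1 coefficient |
| `drift_amplitude` | 1 | SD of the per-voxel drift coefficients |
| `p_remember` | 0.3528 (FM) / 0.4367 (EE) | Bernoulli rate of *remembered* labels, set to the observed mean recognition rates of the two conditions |

All randomness flows from one master seed fanned into named substreams
(design, labels, patterns, per-run noise), so any stage reproduces in
isolation.

Class patterns are drawn **per subject** by default: a stable within-subject
code, which is what within-subject decoding assumes. A direct consequence —
verified by the tests — is that cross-subject decoding of such a cohort is
at chance, because no pattern is shared across brains.
`simulate_subject(patterns = )` accepts one shared pattern set for a whole
cohort to emulate spatially normalized real data, where cross-subject
decoding is possible; the `analysis/` scripts use this to demonstrate the
cross-subject route.

### What the generator does and does not emulate

It reproduces the statistical structure the decoder assumes: trial-locked
hemodynamic responses, temporally autocorrelated noise, slow drift,
run-wise acquisition, and a spatially localized, class-specific multivoxel
code. It does **not** emulate anatomy, motion or physiological artifacts,
slice-timing effects, spatial smoothness of noise, or any perceptual
difference between FM and EE (the two conditions differ only in their
label rates). Passing tests therefore show that the pipeline is correct
and calibrated under its own assumptions — not that real scans would
decode at any particular accuracy.

## Preprocessing choices

- **Baseline reference.** Volumes acquired 6–8 s after baseline-trial
  onsets define the per-voxel mean and SD for z-scoring. Because event
  durations are 9 or 13 s, onsets alternate parity while volumes fall on
  even seconds, so an odd-onset trial's inclusive window contains one
  volume and an even-onset trial's two; the indices come from time
  arithmetic, not a fixed per-trial count. Voxels with zero baseline SD
  are set to 0 and flagged rather than propagating `NaN`.
- **Peak-window aggregation.** The volumes in `[onset + 6, onset + 8]`
  (endpoints inclusive; volume $i$ acquired at $(i-1)\,TR$) are
  *averaged* into one sample per trial, keeping one sample per label and
  making per-run counterbalancing well defined. `aggregate =
  "concatenate"` lays the window volumes side by side instead (trials
  truncated to the smallest in-window count so feature length is
  constant), since the original analysis's aggregation is not recoverable.
- **Counterbalancing.** Within each run the majority class is randomly
  down-sampled to the minority count; single-class runs are dropped with a
  warning. Outputs are always subsets of inputs.

## Decoding choices

- **Feature scoring.** Two-group one-way ANOVA F per voxel,
  $F = MS_{between}/MS_{within}$ with df $(1, n-2)$ — identical to the
  squared pooled t, which the tests exploit as an oracle. Zero
  within-group variance yields `Inf` (always selected) and a flag.
- **Top-k selection.** $k = 100$ by default; ties break to the lowest
  voxel index so runs are reproducible; $k$ larger than the voxel pool
  (small ROIs) is clamped with a warning rather than an error.
- **Nesting.** Selection is recomputed on the training portion of every
  fold. `nested = FALSE` exists solely as a leakage diagnostic: on pure
  noise it inflates accuracy far above chance while the nested path does
  not, and a regression test keeps it that way.
- **Classifier.** `e1071::svm` (libsvm) with a linear kernel, fixed
  $C = 1$, no internal rescaling (inputs are already z-scored), no
  tuning — the original analysis reports none, and the exact 2015-era
  defaults are not recoverable; only qualitative accuracy patterns are.
- **Accuracy bookkeeping.** Per-fold accuracies, their unweighted mean
  (the quantity averaged across subjects in within-subject summaries), and
  the pooled confusion matrix, whose accuracy equals the sample-weighted
  fold mean exactly. Precision is $tp/(tp+fp)$ and the F-score
  $2tp/(2tp+fp+fn)$, positive class *remembered*.

## Permutation inference

Each permutation shuffles the label vector over the whole dataset
(within runs by default for the within-subject scheme, preserving run-wise
balance; plain dataset-wise for cross-subject), retrains every fold —
including feature selection — on the permuted labels, and scores against
the **original** test labels. The p-value is the add-one Monte-Carlo
estimator $p = (1 + \#\{A_{perm} \ge A_{obs}\})/(1 + n_{perm})$, never
exactly zero. Full-scale defaults are 10000 permutations (within subject)
and 1000 (cross subject); reduced counts are supported for desk-scale
work.

One property of this scheme deserves explicit mention. Because the
observed statistic uses one consistent label vector for both training and
testing while each permutation decouples them (training labels permuted,
test labels original), the observed fold-mean accuracy is somewhat
over-dispersed relative to the permutation distribution on null data — we
measure a variance ratio near 1.5 on small three-run datasets — so the
test runs mildly liberal (empirical type-I error around 0.06–0.08 at
$\alpha = 0.05$ in small-sample conditions, nominal under the full
pipeline conditions the calibration test uses). This is inherent to
relabeling only the training portion, which is the procedure as described;
relabeling test folds as well would restore exact exchangeability but
would be a different test. The property tests assert approximate, not
exact, uniformity of null p-values for this reason.

## ROI and searchlight mapping

ROI decoding slices the feature matrix to mask-true voxels (x-fastest grid
order preserved) and reruns the identical pipeline with the same folds for
every region, so regional accuracies are directly comparable; $k$ clamps
to the region size. Anatomical atlases are out of scope — masks are
user-supplied NIfTI volumes or geometric primitives (`sphere_mask`,
`box_mask`), since synthetic brains have no anatomy.

The searchlight iterates over every in-mask center, projects the features
onto the integer-lattice ball of the given radius — radius measured in
voxel-index units, because the documented "4-voxel radius (257 voxels)"
matches the lattice-ball count $|\{o : \|o\|_2 \le 4\}| = 257$ exactly,
ignoring the anisotropic voxel size — and cross-validates with **no**
top-k selection inside the neighborhood (the projection *is* the
selection). Neighborhoods are edge-clipped, computed whenever at least two
voxels remain, and the map is independent of center order. Thresholding is
a per-center one-sided exact binomial test of the implied correct count
against Binomial($n$, 0.5), uncorrected by default (no correction is named
for the original maps); Benjamini–Hochberg FDR is available via
`correction = "fdr"`. `report_peaks` tabulates 6-connected significant
clusters with world-space peak coordinates through the affine.

## Behavioral scoring

4AFC chance is $1/4$, derived from the alternative count everywhere. A
participant is included when the test-1 correct count beats
Binomial($n$, 0.25) and the both-tests-correct count beats
Binomial($n$, 0.0625) — the chance of guessing the same item right twice —
both one-sided at $\alpha = 0.05$. The two-test criterion's exact null is
ambiguous in the source description; the consistency operationalization is
the default and a test-2 marginal variant is exposed
(`both_null = "marginal"`). Items reported as previously familiar are
excluded before any proportion; items with familiar *lures* are not
(matching the stated procedure). Labels for decoding come from the first
test: remembered iff test-1 correct.

## Problem sizes and numerical tolerances

The test and calibration runs use a 16 × 16 × 8 grid (2048 voxels, the
full 748-volume temporal structure) for pipeline-level checks and
8 × 8 × 4 or smaller grids for unit-level checks; calibration repetitions
use 100–200 datasets at 99–200 permutations. These sizes were chosen so
the whole suite exercises every stage at meaningful sample sizes on a
single CPU; they are stated here so results can be reproduced exactly.
Deterministic identities (F vs t², detrending residuals, z-score
idempotence, SVM refits) are asserted at 1e-8–1e-10; stochastic
calibration quantities at the sampling-error scale of their designs
(±0.02–0.06).

## Known limitations

- Cross-subject decoding is only meaningful with shared patterns (see
  above); the default generator deliberately does not provide them.
- The permutation test's mild liberal bias on small datasets, discussed
  above.
- `effect_size = 1` decodes essentially perfectly at desk scale; the
  default is a demonstration amplitude, not an estimate of any real
  subsequent-memory effect.
- Spatial preprocessing (slice timing, realignment, normalization,
  smoothing) is assumed done upstream; the package starts from aligned
  volumes.
- Searchlight inference is per-center and uncorrected by default; cluster
  -extent inference and surface-based searchlights are out of scope.
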