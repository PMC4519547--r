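# submvpa

Subsequent-memory multivoxel pattern analysis (MVPA) for fMRI, with a
synthetic BOLD generator so the whole pipeline runs, and is tested,
without real scans.

The scientific setting is a subsequent-memory design: participants encode
picture–label associations in the scanner — incidentally, through fast
mapping (FM), or intentionally, through explicit encoding (EE) — and
recognition is tested afterwards by 4-alternative forced choice. The
question is whether the multivoxel activity pattern at encoding predicts,
trial by trial, whether the association will later be remembered. The
package is for researchers who want a tested, reproducible implementation
of that analysis — trial-schedule generation, BOLD simulation,
baseline-referenced preprocessing, classification, permutation inference,
ROI-restricted decoding and searchlight mapping — or who want to study the
statistical behavior (calibration, leakage, localization) of this class of
pipeline on data with known ground truth.

## The method

For each novel-item trial, the volumes acquired 6–8 s after stimulus onset
(the hemodynamic peak) are averaged into a feature vector and labeled
*remembered* or *forgotten* from the later recognition test. After
per-voxel detrending, z-scoring against baseline-period volumes, and
per-run class counterbalancing, decoding proceeds per cross-validation
fold:

1. score every voxel with the two-group ANOVA F,
   F = MS_between / MS_within, df (1, n − 2), on training data only;
2. keep the k = 100 top-F voxels;
3. train a linear soft-margin SVM, f(x) = sign(w·x + b), C = 1;
4. score the held-out run (within subject, 3-fold leave-one-run-out) or
   subject (cross subject, leave-one-subject-out).

Significance comes from dataset-wise label permutation — labels shuffled
over the dataset, only training folds relabeled, scored against original
test labels, p = (1 + #{perm ≥ obs}) / (1 + n_perm) — and from per-center
binomial tests against Binomial(n, 0.5) for searchlight maps, where the
classifier runs on each voxel's spherical neighborhood (radius 4 = 257
voxels at full scale) instead of top-k-selected features. Confusion-matrix
metrics use *remembered* as the positive class: precision tp/(tp+fp),
F-score 2tp/(2tp+fp+fn).

The synthetic generator reproduces the acquisition arithmetic exactly
(3 runs of 482/482/532 s → 241/241/266 volumes at TR = 2 s; 124 events,
62 novel targets, mean event duration 11 s) and embeds a class-dependent
multivoxel pattern, convolved with a double-gamma HRF, in configurable
regions over AR(1) noise and drift. See
`vignettes/decoding-subsequent-memory.Rmd` for the model, parameters and
design choices.

## Worked example

```r
library(submvpa)

gd     <- c(16L, 16L, 8L)
region <- sphere_mask(gd, c(5, 5, 4), 3)          # informative region
cfg    <- sim_config(grid_dim = gd, effect_size = 1,
                     informative_regions = list(atl_like = region),
                     seed = 20250926)

sub  <- simulate_subject("FM", cfg)               # design + labels + 3 runs
ss   <- counterbalance(preprocess_subject(sub), seed = 1)
plan <- make_fold_plan(ss, "leave_one_run_out")

cross_validate(ss, plan, k = 100)
#> decoding_result (leave_one_run_out, k = 100): mean accuracy 1.000 over 3 folds

permutation_test(ss, plan, k = 100, n_permutations = 500, seed = 2)
#> permutation_null: observed 1.000, null mean 0.497, p = 0.001996 (500 perms)
```

At the default demonstration amplitude (`effect_size = 1`, one marginal
noise SD at the event peak) the embedded pattern is decoded perfectly and
the permutation p-value hits its add-one floor 1/501. With
`effect_size = 0` the same pipeline sits at chance (0.5) — the
calibration tests hold it there.

The `analysis/` directory runs the full study as numbered steps
(`01_design.R` … `07_behavior.R`), writing tables under `results/`. Step
05, with the pattern confined to one region of a 6-subject cohort,
prints the regional dissociation:

```
      region n_voxels k_used mean_accuracy pooled_accuracy
 whole_brain     2048    100      1.000000        1.000000
    atl_like      123    100      1.000000        1.000000
     control      123    100      0.557215        0.548951
```

The region carrying the signal decodes as well as the whole brain; the
signal-free control region stays at chance — the synthetic analogue of
the ATL/hippocampus dissociation between encoding conditions.

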