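# Shared settings for the analysis scripts: one simulated FM cohort with a
# subsequent-memory pattern confined to a synthetic "ATL-like" region, plus
# a signal-free control region, on a desk-scale 16 x 16 x 8 grid.

library(submvpa)

GRID <- c(16L, 16L, 8L)
REGION_A <- sphere_mask(GRID, c(5, 5, 4), 3)    # carries the class pattern
REGION_B <- sphere_mask(GRID, c(12, 12, 5), 3)  # signal-free control
N_SUBJECTS <- 6
EFFECT_SIZE <- 1
MASTER_SEED <- 20250925

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cohort_config <- function(effect_size = EFFECT_SIZE) {
  sim_config(grid_dim = GRID, effect_size = effect_size,
             informative_regions = list(atl_like = REGION_A),
             seed = MASTER_SEED)
}

# simulate + preprocess + counterbalance the cohort; deterministic. One
# pattern set is shared across subjects (a common informative topography,
# as cross-subject decoding of spatially normalized brains assumes).
simulate_cohort <- function(effect_size = EFFECT_SIZE,
                            n_subjects = N_SUBJECTS) {
  shared <- make_class_patterns(cohort_config(effect_size), MASTER_SEED)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- cohort_config(effect_size)
    cfg$seed <- MASTER_SEED + i
    sub <- simulate_subject("FM", cfg, subject_id = sprintf("sub-%02d", i),
                            patterns = shared)
    counterbalance(preprocess_subject(sub), seed = 1000 + i)
  })
}

write_tsv <- function(df, name) {
  path <- file.path("results", name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  wrote", path, "\n")
}
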