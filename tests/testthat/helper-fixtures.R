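# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# Pure-noise sample set built directly (bypassing BOLD simulation) for
# null-calibration and leakage tests: balanced labels per run, i.i.d.
# standard-normal features carrying no class information.
null_sample_set <- function(n_per_run = 12, n_vox = 60, runs = 3,
                            seed = 1, subject = "sub-01") {
  stopifnot(n_per_run %% 2 == 0)
  gd <- c(n_vox, 1L, 1L)
  submvpa:::with_seed(seed, {
    n <- n_per_run * runs
    lab <- unlist(lapply(seq_len(runs), function(r)
      sample(rep(c("remembered", "forgotten"), n_per_run / 2))))
    sample_set(matrix(rnorm(n * n_vox), n, n_vox), lab,
               rep(seq_len(runs) - 1L, each = n_per_run),
               rep(subject, n),
               sprintf("novel_%03d", seq_len(n)),
               cbind(seq_len(n_vox), 1L, 1L), gd)
  })
}

# Sample set whose first voxel is the label plus small noise: any sane
# classifier reaches accuracy 1.
oracle_sample_set <- function(n_per_run = 10, n_vox = 20, seed = 1) {
  ss <- null_sample_set(n_per_run, n_vox, seed = seed)
  ss$X[, 1] <- ifelse(ss$labels == "remembered", 1, -1) +
    0.01 * ss$X[, 1]
  ss
}

# Small simulated subject for end-to-end tests.
tiny_subject <- function(seed = 1, effect_size = 0, grid = c(8L, 8L, 4L),
                         regions = list(), p_remember = NULL,
                         condition = "FM") {
  simulate_subject(condition,
                   sim_config(grid_dim = grid, effect_size = effect_size,
                              informative_regions = regions,
                              p_remember = p_remember, seed = seed))
}

# Brute-force lattice ball enumeration: the independent oracle for
# sphere_offsets.
brute_force_ball <- function(radius) {
  r <- floor(radius)
  out <- matrix(0L, 0, 3)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
    if (dx^2 + dy^2 + dz^2 <= radius^2)
      out <- rbind(out, c(dx, dy, dz))
  out
}
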