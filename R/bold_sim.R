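# Synthetic 4D BOLD generation. Each run is baseline + AR(1) noise + slow
# drift, with a class-dependent multivoxel pattern added inside designated
# informative regions on every novel-target trial: a fixed per-subject
# pattern vector per class, modulated by a 3.5 s boxcar (picture + response
# window) convolved with a canonical double-gamma hemodynamic response.

#' Canonical double-gamma hemodynamic response function
#'
#' `hrf(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with gamma-density kernels, the
#' standard positive lobe peaking near 5 s with a late undershoot around
#' 15 s. `hrf(0) = 0` and the response decays to 0 for large `t`.
#'
#' @param t Time in seconds since event onset; must be >= 0.
#' @return Response amplitude (arbitrary units) at each `t`.
#' @export
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(hrf(tt))]  # ~5 s
hrf <- function(t) {
  if (any(t < 0)) stop_submvpa("hrf is defined for t >= 0 only")
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Simulation configuration
#'
#' Bundles the acquisition geometry, noise model and ground-truth signal
#' parameters consumed by [simulate_run()] and [simulate_subject()].
#'
#' @param grid_dim Integer 3-vector, volume grid shape. The scanned
#'   acquisition this emulates used a 64 x 64 x 32 grid; the default is a
#'   reduced 16 x 16 x 8 grid that preserves the temporal structure at
#'   desk scale.
#' @param TR Repetition time, seconds.
#' @param voxel_size mm edge lengths (3 x 3 x 5 mm acquisition voxels).
#' @param informative_regions Named list of 3D logical arrays (same shape as
#'   `grid_dim`) marking where the class-dependent pattern is embedded.
#' @param effect_size Peak amplitude of the class pattern in units of the
#'   marginal noise SD; 0 means no class information anywhere.
#' @param noise_sd Innovation SD of the AR(1) voxel noise.
#' @param ar1_coef Lag-1 autoregressive coefficient in `[0, 1)`.
#' @param drift_amplitude SD of per-voxel linear and slow-cosine drift
#'   coefficients.
#' @param baseline_mean Additive constant (raw-intensity floor).
#' @param p_remember Probability that a novel-target trial is subsequently
#'   remembered. `NULL` uses the condition-specific observed recognition
#'   rates (FM 0.3528, EE 0.4367).
#' @param seed Master seed; design, labels, patterns and noise each draw
#'   from a named substream derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_dim = c(16L, 16L, 8L), TR = 2,
                       voxel_size = c(3, 3, 5),
                       informative_regions = list(),
                       effect_size = 1, noise_sd = 1, ar1_coef = 0.3,
                       drift_amplitude = 1, baseline_mean = 100,
                       p_remember = NULL, seed = 1L) {
  stopifnot(length(grid_dim) == 3, TR > 0, effect_size >= 0, noise_sd > 0,
            ar1_coef >= 0, ar1_coef < 1, drift_amplitude >= 0)
  if (!is.null(p_remember))
    stopifnot(p_remember >= 0, p_remember <= 1)
  for (m in informative_regions)
    if (!identical(dim(m), as.integer(grid_dim)))
      stop_submvpa("informative region shape does not match grid_dim")
  structure(list(grid_dim = as.integer(grid_dim), TR = TR,
                 voxel_size = voxel_size,
                 informative_regions = informative_regions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 ar1_coef = ar1_coef, drift_amplitude = drift_amplitude,
                 baseline_mean = baseline_mean, p_remember = p_remember,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_affine <- function(config) {
  a <- diag(c(config$voxel_size, 1))
  a
}

.default_p_remember <- c(FM = 0.3528, EE = 0.4367)

# Single-event reference response: 3.5 s boxcar (picture 2 s + response
# 1.5 s) convolved with the HRF, normalized to peak 1 so that effect_size
# is the per-event peak amplitude in noise-SD units.
.event_regressor <- function(onsets, n_vol, TR, dt = 0.1) {
  dur <- 3.5
  n_hi <- ceiling(n_vol * TR / dt) + 1L
  kern <- hrf(seq(0, 32, by = dt)) * dt
  ref <- stats::convolve(c(rep(1, round(dur / dt)),
                           rep(0, length(kern))), rev(kern), type = "open")
  scale <- max(ref)
  x <- numeric(n_hi + length(kern))
  for (o in onsets) {
    i0 <- floor(o / dt) + 1L
    i1 <- min(i0 + round(dur / dt) - 1L, length(x))
    x[i0:i1] <- x[i0:i1] + 1
  }
  conv <- stats::convolve(x, rev(kern), type = "open")[seq_len(n_hi)] / scale
  conv[floor((seq_len(n_vol) - 1L) * TR / dt) + 1L]
}

#' Draw the per-subject class pattern vectors
#'
#' One fixed standard-normal pattern per class per informative region,
#' reused across all runs of the subject (the decodable signal is a stable
#' spatial pattern, not trial-specific activity).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the pattern substream.
#' @return Named list per region: `voxels` (linear indices into the grid),
#'   `remembered`, `forgotten` (pattern vectors).
#' @export
make_class_patterns <- function(config, seed) {
  with_seed(seed, lapply(config$informative_regions, function(mask) {
    vox <- which(mask)
    list(voxels = vox,
         remembered = stats::rnorm(length(vox)),
         forgotten = stats::rnorm(length(vox)))
  }))
}

#' Simulate one BOLD run
#'
#' @param run_design A `run_design` (one element of
#'   `make_subject_design()$runs`).
#' @param truth Data frame `stimulus_id`, `true_label` covering the novel
#'   trials (see [simulate_subject()]).
#' @param config A [sim_config()].
#' @param patterns Class patterns from [make_class_patterns()]; `NULL`
#'   draws them from the config's pattern substream.
#' @param noise_seed Seed for this run's noise substream.
#' @param subject_id Carried into the returned series.
#' @return A `volume_series`: 4D array `(nx, ny, nz, nt)` plus `TR`,
#'   `affine`, `run_index`, `subject_id`.
#' @export
simulate_run <- function(run_design, truth, config, patterns = NULL,
                         noise_seed = config$seed, subject_id = "sub-01") {
  stopifnot(inherits(run_design, "run_design"), inherits(config, "sim_config"))
  if (is.null(patterns))
    patterns <- make_class_patterns(config,
                                    derive_seeds(config$seed, "patterns"))
  nvox <- prod(config$grid_dim)
  nt <- run_design$n_volumes
  tv <- (seq_len(nt) - 1L) * config$TR
  tmax <- run_design$total_duration

  dat <- with_seed(noise_seed, {
    innov <- matrix(stats::rnorm(nt * nvox, sd = config$noise_sd), nt, nvox)
    noise <- if (config$ar1_coef > 0)
      apply(innov, 2, function(x)
        as.numeric(stats::filter(x, config$ar1_coef, method = "recursive")))
    else innov
    lin <- tv / tmax - 0.5
    cosv <- cos(pi * tv / tmax)
    a <- stats::rnorm(nvox, sd = config$drift_amplitude)
    b <- stats::rnorm(nvox, sd = config$drift_amplitude)
    noise + outer(lin, a) + outer(cosv, b) + config$baseline_mean
  })

  if (config$effect_size > 0 && length(patterns) > 0) {
    ev <- run_design$events
    novel <- ev[ev$trial_type == "novel_target", ]
    lab <- truth$true_label[match(novel$stimulus_id, truth$stimulus_id)]
    if (anyNA(lab))
      stop_submvpa("truth table does not cover all novel trials of the run")
    amp <- config$effect_size * config$noise_sd /
      sqrt(1 - config$ar1_coef^2)
    for (cls in c("remembered", "forgotten")) {
      onsets <- novel$onset[lab == cls]
      if (length(onsets) == 0) next
      reg <- .event_regressor(onsets, nt, config$TR)
      for (p in patterns) {
        if (max(p$voxels) > nvox)
          stop_submvpa("informative region does not fit the grid")
        dat[, p$voxels] <- dat[, p$voxels] + amp * outer(reg, p[[cls]])
      }
    }
  }

  structure(list(data = array(t(dat), c(config$grid_dim, nt)),
                 TR = config$TR, affine = .sim_affine(config),
                 run_index = run_design$run_index, subject_id = subject_id),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %s run %d, grid %dx%dx%d, %d volumes, TR %g s\n",
              x$subject_id, x$run_index, d[1], d[2], d[3], d[4], x$TR))
  invisible(x)
}

#' Simulate a full subject: design, labels, three BOLD runs
#'
#' Novel-trial subsequent-memory labels are drawn i.i.d.
#' Bernoulli(`p_remember`); class patterns are fixed per subject.
#'
#' @param condition `"FM"` or `"EE"`.
#' @param config A [sim_config()].
#' @param subject_id Identifier string.
#' @param patterns Optional class patterns from [make_class_patterns()].
#'   The default (`NULL`) draws subject-specific patterns — decodable
#'   within subject but not across subjects. Passing one shared pattern set
#'   to every subject emulates a cohort whose informative topography is
#'   common across (spatially normalized) brains, which cross-subject
#'   decoding requires.
#' @return List with `design` (`subject_design`), `volumes` (list of 3
#'   `volume_series`), `events` (per-run tables), `truth` (stimulus_id,
#'   true_label) and `config`.
#' @export
simulate_subject <- function(condition = c("FM", "EE"), config,
                             subject_id = "sub-01", patterns = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed,
                        c("design", "labels", "patterns",
                          "noise1", "noise2", "noise3"))
  design <- make_subject_design(condition, seeds[["design"]], TR = config$TR)
  novel_ids <- unlist(lapply(design$runs, function(r)
    r$events$stimulus_id[r$events$trial_type == "novel_target"]))
  p_rem <- config$p_remember %||% .default_p_remember[[condition]]
  labels <- with_seed(seeds[["labels"]],
                      ifelse(stats::runif(length(novel_ids)) < p_rem,
                             "remembered", "forgotten"))
  truth <- data.frame(stimulus_id = novel_ids, true_label = labels,
                      stringsAsFactors = FALSE)
  if (is.null(patterns))
    patterns <- make_class_patterns(config, seeds[["patterns"]])
  volumes <- lapply(1:3, function(r)
    simulate_run(design$runs[[r]], truth, config, patterns,
                 noise_seed = seeds[[paste0("noise", r)]],
                 subject_id = subject_id))
  list(design = design, volumes = volumes,
       events = design_to_events_table(design), truth = truth,
       config = config, subject_id = subject_id)
}

#' Write a simulated subject to a BIDS-like directory layout
#'
#' Produces `sub-XX/func/run-{1,2,3}_bold.nii.gz`, per-run
#' `run-*_events.tsv`, `truth.tsv` and `config.json`.
#'
#' @param subject Result of [simulate_subject()].
#' @param dir Output directory (created if needed).
#' @return The subject directory path, invisibly.
#' @export
write_subject <- function(subject, dir) {
  sdir <- file.path(dir, subject$subject_id, "func")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (r in 1:3) {
    vs <- subject$volumes[[r]]
    img <- RNifti::asNifti(vs$data)
    RNifti::pixdim(img) <- c(subject$config$voxel_size, vs$TR)
    RNifti::writeNifti(img, file.path(sdir, sprintf("run-%d_bold.nii.gz", r)))
    write_events_tsv(subject$events[[r]],
                     file.path(sdir, sprintf("run-%d_events.tsv", r)))
  }
  utils::write.table(subject$truth,
                     file.path(dir, subject$subject_id, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- subject$config
  cfg$informative_regions <- lapply(cfg$informative_regions, function(m)
    list(n_voxels = sum(m)))
  jsonlite::write_json(unclass(cfg),
                       file.path(dir, subject$subject_id, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, subject$subject_id))
}
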