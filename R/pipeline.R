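# End-to-end orchestration: simulate -> preprocess -> decode / roi /
# searchlight -> permutation inference, from one declarative configuration
# with full seed provenance. The numbered scripts under analysis/ are thin
# drivers over these functions.

#' Preprocess a simulated (or loaded) subject into a sample set
#'
#' Per run: baseline-period volume indices, detrend + baseline-referenced
#' z-scoring, peak-window trial extraction; runs are then pooled into one
#' per-subject `sample_set`.
#'
#' @param subject List as returned by [simulate_subject()] (`design`,
#'   `volumes`, `events`, `truth`).
#' @param window Peak window in seconds post onset.
#' @param mask Optional 3D logical analysis mask.
#' @param aggregate Peak-volume aggregation mode (see
#'   [extract_trial_samples()]).
#' @return A `sample_set` covering the subject's three runs.
#' @export
preprocess_subject <- function(subject, window = c(6, 8), mask = NULL,
                               aggregate = "average") {
  sets <- lapply(1:3, function(r) {
    vs <- detrend_and_zscore(
      subject$volumes[[r]],
      baseline_volume_indices(subject$design$runs[[r]], window))
    extract_trial_samples(vs, subject$events[[r]], subject$truth,
                          window = window, mask = mask,
                          aggregate = aggregate,
                          subject_id = subject$subject_id)
  })
  combine_sample_sets(sets)
}

#' Experiment configuration
#'
#' Validated bundle of every knob the pipeline exposes. Serialized verbatim
#' into the output directory of [run_experiment()].
#'
#' @param condition `"FM"` or `"EE"`.
#' @param n_subjects Simulated subjects.
#' @param sim A [sim_config()] template; its seed is re-derived per subject
#'   from `seed`.
#' @param k Feature-selection count.
#' @param C SVM cost.
#' @param radius Searchlight radius (voxel units).
#' @param alpha Significance level for map thresholding.
#' @param n_permutations Permutations for significance testing.
#' @param window Peak window, seconds post onset.
#' @param aggregate `"average"` or `"concatenate"`.
#' @param masks Named list of ROI masks (3D logical), may be empty.
#' @param run_searchlight Compute the searchlight map (on the first
#'   subject) — the costliest stage.
#' @param seed Master seed for the whole experiment.
#' @return A `run_config`.
#' @export
run_config <- function(condition = "FM", n_subjects = 4, sim = sim_config(),
                       k = 100L, C = 1, radius = 2, alpha = 0.05,
                       n_permutations = 200L, window = c(6, 8),
                       aggregate = "average", masks = list(),
                       run_searchlight = FALSE, seed = 1L) {
  stopifnot(condition %in% c("FM", "EE"), n_subjects >= 1,
            inherits(sim, "sim_config"), k >= 1, radius >= 1,
            alpha > 0, alpha < 1, n_permutations >= 1,
            length(window) == 2, window[1] <= window[2],
            aggregate %in% c("average", "concatenate"))
  if (length(masks) > 0 && is.null(names(masks)))
    stop_submvpa("masks must be named")
  structure(list(condition = condition, n_subjects = n_subjects, sim = sim,
                 k = as.integer(k), C = C, radius = radius, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 window = window, aggregate = aggregate, masks = masks,
                 run_searchlight = run_searchlight, seed = as.integer(seed)),
            class = "run_config")
}

#' Run a full simulated decoding experiment
#'
#' Simulates `n_subjects` subjects, preprocesses and counterbalances them,
#' and runs (i) within-subject leave-one-run-out decoding averaged across
#' subjects, (ii) cross-subject leave-one-subject-out decoding on the
#' pooled set, (iii) a permutation test for each scheme, (iv) the ROI
#' battery on the pooled set when masks are supplied, and (v) optionally a
#' searchlight map on the first subject. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, tabular results are
#'   written as TSV, summaries and the config as JSON, and maps as NIfTI.
#' @return List: `subjects` (sample sets), `within`, `cross`,
#'   `permutation` (per scheme), `roi`, `searchlight`, `peaks`, `seeds`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed,
                        c("subjects", "counterbalance", "perm_within",
                          "perm_cross"))
  subj_seeds <- derive_seeds(seeds[["subjects"]],
                             sprintf("sub%02d", seq_len(config$n_subjects)))
  sets <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sim <- config$sim
    sim$seed <- subj_seeds[[i]]
    subj <- simulate_subject(config$condition, sim,
                             subject_id = sprintf("sub-%02d", i))
    ss <- preprocess_subject(subj, window = config$window,
                             aggregate = config$aggregate)
    sets[[i]] <- counterbalance(ss, seeds[["counterbalance"]] + i)
  }

  within <- decode_within_subjects(sets, k = config$k, C = config$C)
  pooled <- combine_sample_sets(sets)
  cross_plan <- make_fold_plan(pooled, "leave_one_subject_out")
  cross <- cross_validate(pooled, cross_plan, k = config$k, C = config$C)

  perm_within <- permutation_test(
    sets[[1]], make_fold_plan(sets[[1]], "leave_one_run_out"),
    k = config$k, C = config$C, n_permutations = config$n_permutations,
    seed = seeds[["perm_within"]], observed = within$results[[1]])
  perm_cross <- if (config$n_subjects >= 2) permutation_test(
    pooled, cross_plan, k = config$k, C = config$C,
    n_permutations = config$n_permutations,
    seed = seeds[["perm_cross"]], stratify_by_run = FALSE,
    observed = cross) else NULL

  roi <- if (length(config$masks) > 0)
    roi_battery(pooled, config$masks, cross_plan, k = config$k,
                C = config$C) else NULL

  sl <- peaks <- NULL
  if (config$run_searchlight) {
    sl <- searchlight_map(sets[[1]],
                          make_fold_plan(sets[[1]], "leave_one_run_out"),
                          radius = config$radius, C = config$C)
    sl <- threshold_map(sl, alpha = config$alpha)
    peaks <- report_peaks(sl)
  }

  out <- list(subjects = sets, within = within, cross = cross,
              permutation = list(within = perm_within, cross = perm_cross),
              roi = roi, searchlight = sl, peaks = peaks,
              seeds = c(master = config$seed, seeds),
              config = config)
  if (!is.null(out_dir)) .write_experiment(out, out_dir)
  out
}

.write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  dec <- rbind(
    data.frame(scheme = "within_subject",
               unit = names(res$within$per_subject),
               accuracy = unname(res$within$per_subject)),
    data.frame(scheme = "cross_subject",
               unit = sprintf("fold_%d",
                              seq_along(res$cross$fold_accuracy)),
               accuracy = res$cross$fold_accuracy))
  tsv(dec, "decoding_results.tsv")
  cms <- lapply(c(res$within$results, list(res$cross)), `[[`, "confusion")
  conf <- do.call(rbind, lapply(seq_along(cms), function(i) {
    cm <- cms[[i]]
    data.frame(unit = if (i <= length(res$within$results))
                 names(res$within$per_subject)[i] else "cross_subject",
               tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
               precision = precision(cm), f_score = f_score(cm),
               accuracy = accuracy(cm))
  }))
  tsv(conf, "confusion.tsv")
  for (sch in names(res$permutation)) {
    pn <- res$permutation[[sch]]
    if (is.null(pn)) next
    tsv(data.frame(permutation = seq_along(pn$permuted_accuracies),
                   accuracy = pn$permuted_accuracies),
        sprintf("permutation_%s.tsv", sch))
    jsonlite::write_json(
      list(scheme = sch, observed = pn$observed_accuracy,
           p_value = pn$p_value, n_permutations = pn$n_permutations),
      file.path(out_dir, sprintf("permutation_%s.json", sch)),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$roi)) tsv(res$roi$table, "roi_results.tsv")
  if (!is.null(res$searchlight)) {
    write_accuracy_map_nifti(res$searchlight,
                             file.path(out_dir, "searchlight_accuracy.nii.gz"))
    tsv(res$peaks, "searchlight_peaks.tsv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("submvpa")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seeds = as.list(res$seeds),
    config = list(condition = cfg$condition, n_subjects = cfg$n_subjects,
                  grid_dim = cfg$sim$grid_dim, effect_size = cfg$sim$effect_size,
                  k = cfg$k, C = cfg$C, radius = cfg$radius,
                  alpha = cfg$alpha, n_permutations = cfg$n_permutations,
                  window = cfg$window, aggregate = cfg$aggregate,
                  masks = names(cfg$masks),
                  run_searchlight = cfg$run_searchlight, seed = cfg$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
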