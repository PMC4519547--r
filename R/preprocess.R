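# Baseline-referenced preprocessing and trial extraction: detrend each
# voxel, z-score against baseline-period volumes, average the volumes in the
# hemodynamic peak window (6-8 s post stimulus onset) into one labeled
# feature vector per novel-target trial, then equalize class counts per run.

#' Construct a sample set
#'
#' Labeled trial feature vectors with run/subject provenance. Feature order
#' is defined by `voxel_index` (x-fastest grid scan, 1-based coordinates).
#'
#' @param X Numeric matrix, trials x voxels.
#' @param labels Character/factor, `"remembered"` / `"forgotten"`.
#' @param run Integer run index per trial.
#' @param subject Subject id per trial.
#' @param stimulus_id Stimulus token per trial.
#' @param voxel_index Integer matrix `p x 3` of grid coordinates.
#' @param grid_dim Grid shape the coordinates refer to.
#' @return A `sample_set`.
#' @export
sample_set <- function(X, labels, run, subject, stimulus_id, voxel_index,
                       grid_dim) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels),
                   levels = c("forgotten", "remembered"))
  stopifnot(nrow(X) == length(labels), nrow(X) == length(run),
            ncol(X) == nrow(voxel_index), !anyNA(labels))
  if (anyDuplicated(voxel_index))
    stop_submvpa("voxel_index contains duplicate coordinates")
  structure(list(X = X, labels = labels, run = as.integer(run),
                 subject = as.character(subject),
                 stimulus_id = as.character(stimulus_id),
                 voxel_index = voxel_index,
                 grid_dim = as.integer(grid_dim)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d samples x %d voxels, %d run(s), %d subject(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$run)),
              length(unique(x$subject))))
  print(table(x$labels))
  invisible(x)
}

n_samples <- function(ss) nrow(ss$X)

#' Row-subset a sample set
#' @param ss A `sample_set`.
#' @param idx Row indices to keep.
#' @return The subset `sample_set`.
#' @export
subset_samples <- function(ss, idx) {
  sample_set(ss$X[idx, , drop = FALSE], ss$labels[idx], ss$run[idx],
             ss$subject[idx], ss$stimulus_id[idx], ss$voxel_index,
             ss$grid_dim)
}

#' Pool sample sets from several subjects into one
#'
#' Subjects must share the voxel space (same grid and voxel order);
#' synthetic subjects share the grid by construction, real data are assumed
#' spatially normalized upstream.
#'
#' @param sets List of `sample_set` objects.
#' @return One pooled `sample_set`.
#' @export
combine_sample_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  vi <- sets[[1]]$voxel_index
  for (s in sets[-1])
    if (!identical(s$voxel_index, vi))
      stop_submvpa("sample sets do not share a common voxel space")
  sample_set(do.call(rbind, lapply(sets, `[[`, "X")),
             unlist(lapply(sets, function(s) as.character(s$labels))),
             unlist(lapply(sets, `[[`, "run")),
             unlist(lapply(sets, `[[`, "subject")),
             unlist(lapply(sets, `[[`, "stimulus_id")),
             vi, sets[[1]]$grid_dim)
}

#' Indices of baseline-period volumes in a run
#'
#' Volumes acquired during the hemodynamic peak window of baseline trials
#' (`[onset + window[1], onset + window[2]]`, endpoints inclusive; volume
#' `i` is acquired at `(i - 1) * TR`). Lead-in volumes never qualify since
#' the first event starts after the lead-in.
#'
#' @param run_design A `run_design`.
#' @param window Seconds post onset, default `c(6, 8)`.
#' @return Sorted 1-based volume indices.
#' @export
baseline_volume_indices <- function(run_design, window = c(6, 8)) {
  stopifnot(inherits(run_design, "run_design"))
  ev <- run_design$events
  onsets <- ev$onset[ev$trial_type == "baseline"]
  TR <- run_design$TR
  idx <- unlist(lapply(onsets, function(o) {
    i <- seq(ceiling((o + window[1]) / TR), floor((o + window[2]) / TR))
    i[i >= 0 & i < run_design$n_volumes] + 1L
  }))
  sort(unique(idx))
}

#' Detrend and baseline-referenced z-score a run
#'
#' Per voxel: the least-squares linear trend over the run is removed, then
#' values are standardized by the mean and SD computed over baseline-period
#' volumes only. Voxels with zero baseline SD are set to 0 and flagged in
#' the `zero_variance_voxels` attribute.
#'
#' @param vs A `volume_series`.
#' @param baseline_idx 1-based volume indices from
#'   [baseline_volume_indices()]; at least 2 required.
#' @param detrend Remove the linear trend first (default `TRUE`).
#' @return The transformed `volume_series`.
#' @export
detrend_and_zscore <- function(vs, baseline_idx, detrend = TRUE) {
  stopifnot(inherits(vs, "volume_series"))
  if (length(baseline_idx) < 2)
    stop_submvpa("at least 2 baseline volumes are required for z-scoring")
  d <- dim(vs$data)
  nt <- d[4]
  if (any(baseline_idx < 1 | baseline_idx > nt))
    stop_submvpa("baseline indices outside the run")
  X <- matrix(vs$data, prod(d[1:3]), nt)  # voxels x time
  if (detrend) {
    tc <- seq_len(nt) - (nt + 1) / 2
    slope <- (X %*% tc) / sum(tc^2)
    X <- X - rowMeans(X) - tcrossprod(slope, tc)
  }
  B <- X[, baseline_idx, drop = FALSE]
  mu <- rowMeans(B)
  sd <- sqrt(rowSums((B - mu)^2) / (length(baseline_idx) - 1))
  zero <- sd == 0
  sd[zero] <- 1
  X <- (X - mu) / sd
  X[zero, ] <- 0
  vs$data <- array(X, d)
  attr(vs, "zero_variance_voxels") <- which(zero)
  vs
}

.grid_voxel_index <- function(grid_dim) {
  as.matrix(expand.grid(x = seq_len(grid_dim[1]), y = seq_len(grid_dim[2]),
                        z = seq_len(grid_dim[3]), KEEP.OUT.ATTRS = FALSE))
}

#' Extract peak-window trial samples from a run
#'
#' For each novel-target trial, the volumes acquired within
#' `[onset + window[1], onset + window[2]]` (inclusive) are averaged into a
#' single feature vector (`aggregate = "average"`, the default, keeping one
#' sample per trial to match per-trial labels), or laid side by side
#' (`aggregate = "concatenate"`; trials are truncated to the smallest
#' in-window volume count so feature length stays constant). Trials whose
#' window extends past the end of the run are dropped with a warning.
#'
#' @param vs A (preprocessed) `volume_series`.
#' @param events Events table for the run ([design_to_events_table()]).
#' @param truth Data frame `stimulus_id`, `true_label` supplying labels;
#'   novel trials absent from it are dropped.
#' @param window Seconds post onset, default `c(6, 8)`.
#' @param mask Optional 3D logical array restricting voxels.
#' @param aggregate `"average"` or `"concatenate"`.
#' @param subject_id Provenance tag.
#' @return A `sample_set` (one row per retained trial).
#' @export
extract_trial_samples <- function(vs, events, truth, window = c(6, 8),
                                  mask = NULL,
                                  aggregate = c("average", "concatenate"),
                                  subject_id = vs$subject_id) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(vs, "volume_series"))
  d <- dim(vs$data)
  grid_dim <- d[1:3]
  if (!is.null(mask) && !identical(dim(mask), as.integer(grid_dim)) &&
      !identical(dim(mask), grid_dim))
    stop_submvpa("mask shape does not match volume grid")
  vox_lin <- if (is.null(mask)) seq_len(prod(grid_dim)) else which(mask)
  if (length(vox_lin) == 0) stop_submvpa("mask selects no voxels")
  Xfull <- matrix(vs$data, prod(grid_dim), d[4])[vox_lin, , drop = FALSE]

  novel <- events[events$trial_type == "novel_target", , drop = FALSE]
  lab <- truth$true_label[match(novel$stimulus_id, truth$stimulus_id)]
  keep <- !is.na(lab)
  novel <- novel[keep, , drop = FALSE]
  lab <- lab[keep]

  TR <- vs$TR
  win_idx <- lapply(novel$onset, function(o) {
    i <- seq(ceiling((o + window[1]) / TR), floor((o + window[2]) / TR)) + 1L
    i[i >= 1]
  })
  in_run <- vapply(win_idx, function(i) length(i) > 0 && max(i) <= d[4],
                   logical(1))
  if (!all(in_run)) {
    warning(sum(!in_run), " trial(s) dropped: peak window exceeds run end")
    novel <- novel[in_run, , drop = FALSE]
    lab <- lab[in_run]
    win_idx <- win_idx[in_run]
  }
  if (nrow(novel) == 0) stop_submvpa("no extractable trials in run")

  if (aggregate == "average") {
    feats <- t(vapply(win_idx, function(i)
      rowMeans(Xfull[, i, drop = FALSE]), numeric(length(vox_lin))))
  } else {
    n_keep <- min(lengths(win_idx))
    feats <- t(vapply(win_idx, function(i)
      as.numeric(Xfull[, i[seq_len(n_keep)], drop = FALSE]),
      numeric(length(vox_lin) * n_keep)))
  }
  vi <- .grid_voxel_index(grid_dim)[vox_lin, , drop = FALSE]
  rownames(vi) <- NULL
  if (aggregate == "average")
    return(sample_set(feats, lab, rep(vs$run_index, nrow(feats)),
                      rep(subject_id, nrow(feats)), novel$stimulus_id,
                      vi, grid_dim))
  # concatenate mode: coordinates legally repeat (one block per window
  # volume), so the sample_set is assembled without the duplicate check
  vi <- do.call(rbind, replicate(ncol(feats) / nrow(vi), vi,
                                 simplify = FALSE))
  structure(list(X = feats,
                 labels = factor(lab, c("forgotten", "remembered")),
                 run = rep(vs$run_index, nrow(feats)),
                 subject = rep(subject_id, nrow(feats)),
                 stimulus_id = novel$stimulus_id,
                 voxel_index = vi, grid_dim = as.integer(grid_dim)),
            class = "sample_set")
}

#' Equalize class counts within each run
#'
#' The majority class of every run is randomly down-sampled to the minority
#' count so chance performance is 0.5. Runs containing a single class are
#' excluded with a warning.
#'
#' @param ss A `sample_set`.
#' @param seed Integer seed for the random down-sampling.
#' @return The counterbalanced `sample_set` (a subset of the input).
#' @export
counterbalance <- function(ss, seed) {
  stopifnot(inherits(ss, "sample_set"))
  keys <- paste(ss$subject, ss$run)
  keep <- integer(0)
  dropped <- character(0)
  sel_seeds <- derive_seeds(seed, unique(keys))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    tab <- table(ss$labels[idx])
    if (any(tab == 0)) {
      dropped <- c(dropped, k)
      next
    }
    m <- min(tab)
    chosen <- unlist(lapply(levels(ss$labels), function(cl) {
      cand <- idx[ss$labels[idx] == cl]
      if (length(cand) > m)
        with_seed(sel_seeds[[k]] + match(cl, levels(ss$labels)),
                  sample(cand, m))
      else cand
    }))
    keep <- c(keep, sort(chosen))
  }
  if (length(dropped) > 0)
    warning("run(s) dropped (single class present): ",
            paste(dropped, collapse = ", "))
  if (length(keep) == 0) stop_submvpa("no runs with both classes present")
  subset_samples(ss, sort(keep))
}
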