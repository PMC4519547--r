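# Trial schedule generation for the fast-mapping / explicit-encoding
# subsequent-memory design: 124 events per subject in 3 runs, each event a
# fixed 3 + 2 + 1.5 + 0.5 s stage train followed by a 2 s or 6 s fixation.

.STAGE_DURS <- c(question = 3, picture = 2, response = 1.5, feedback = 0.5)
.LEAD_IN <- 12
.SEQ_BLANK <- 6
.TRIAL_TYPES <- c("novel_target", "familiar_target", "baseline")

#' Compose one pseudorandomized trial sequence
#'
#' A full sequence of 8 events holds 4 novel targets, 2 familiar targets and
#' 2 baseline trials; the short 4-event sequence (end of run 3) holds 2/1/1.
#' Order is a uniform shuffle under the seed. Fixation durations are not
#' assigned here: the 2 s / 6 s split is balanced at run level by the caller.
#'
#' @param n_events Sequence length, 8 or 4.
#' @param seed Integer seed controlling the shuffle.
#' @return Character vector of trial types, length `n_events`.
#' @export
#' @examples
#' table(make_sequence(8, seed = 1))
make_sequence <- function(n_events, seed) {
  if (!n_events %in% c(8L, 4L))
    stop_submvpa("n_events must be 8 or 4, got ", n_events)
  counts <- if (n_events == 8L) c(4L, 2L, 2L) else c(2L, 1L, 1L)
  types <- rep(.TRIAL_TYPES, times = counts)
  with_seed(seed, sample(types))
}

.make_run_design <- function(run_index, seed, TR = 2) {
  seeds <- derive_seeds(seed, c("seq1", "seq2", "seq3", "seq4", "seq5",
                                "seq6", "fixation"))
  seq_sizes <- if (run_index == 2L) c(8L, 8L, 8L, 8L, 8L, 4L)
               else c(8L, 8L, 8L, 8L, 8L)
  types <- character(0)
  seq_index <- integer(0)
  for (i in seq_along(seq_sizes)) {
    types <- c(types, make_sequence(seq_sizes[i], seeds[[i]]))
    seq_index <- c(seq_index, rep(i - 1L, seq_sizes[i]))
  }
  n <- length(types)
  # exactly half the run's events get the short fixation, half the long one
  fixation <- with_seed(seeds[["fixation"]],
                        sample(rep(c(2, 6), each = n / 2)))
  dur <- sum(.STAGE_DURS) + fixation
  onset <- numeric(n)
  t <- .LEAD_IN
  for (i in seq_len(n)) {
    onset[i] <- t
    t <- t + dur[i]
    last_in_seq <- i == n || seq_index[i + 1L] != seq_index[i]
    if (last_in_seq) t <- t + .SEQ_BLANK
  }
  total <- t
  if (total %% TR != 0)
    stop_submvpa("run duration ", total, " s is not a multiple of TR = ", TR)
  events <- data.frame(
    trial_type = types,
    onset = onset,
    question_dur = .STAGE_DURS[["question"]],
    picture_dur = .STAGE_DURS[["picture"]],
    response_dur = .STAGE_DURS[["response"]],
    feedback_dur = .STAGE_DURS[["feedback"]],
    fixation_dur = fixation,
    duration = dur,
    sequence_index = seq_index,
    run_index = run_index,
    stringsAsFactors = FALSE
  )
  structure(list(run_index = run_index, lead_in = .LEAD_IN, events = events,
                 inter_sequence_blank = .SEQ_BLANK, total_duration = total,
                 TR = TR, n_volumes = as.integer(total / TR)),
            class = "run_design")
}

#' Generate a complete subject trial schedule
#'
#' Three runs: runs 1 and 2 hold 40 events (five 8-event sequences) and last
#' 482 s; run 3 holds 44 events (an extra 4-event sequence) and lasts 532 s.
#' Across the subject there are 62 novel targets, 31 familiar targets and 31
#' baseline trials. Stimulus identities are synthetic tokens
#' (`novel_001`, ...), numbered in order of first presentation.
#'
#' @param condition `"FM"` (fast mapping) or `"EE"` (explicit encoding).
#'   The schedule structure is identical; the label travels with the design.
#' @param seed Master integer seed; run composition, orders and fixation
#'   assignments all derive from it.
#' @param TR Repetition time in seconds (volume sampling interval).
#' @return A `subject_design`: list of 3 `run_design` objects plus metadata.
#' @export
#' @examples
#' d <- make_subject_design("FM", seed = 7)
#' vapply(d$runs, `[[`, 0L, "n_volumes")
make_subject_design <- function(condition = c("FM", "EE"), seed, TR = 2) {
  condition <- match.arg(condition)
  run_seeds <- derive_seeds(seed, c("run1", "run2", "run3"))
  runs <- lapply(0:2, function(r) .make_run_design(r, run_seeds[r + 1L], TR))
  counters <- c(novel_target = 0L, familiar_target = 0L, baseline = 0L)
  prefix <- c(novel_target = "novel", familiar_target = "familiar",
              baseline = "baseline")
  for (r in seq_along(runs)) {
    tt <- runs[[r]]$events$trial_type
    ids <- character(length(tt))
    for (i in seq_along(tt)) {
      counters[tt[i]] <- counters[tt[i]] + 1L
      ids[i] <- sprintf("%s_%03d", prefix[tt[i]], counters[tt[i]])
    }
    runs[[r]]$events$stimulus_id <- ids
  }
  structure(list(condition = condition, seed = seed, TR = TR, runs = runs),
            class = "subject_design")
}

#' @export
print.subject_design <- function(x, ...) {
  cat(sprintf("subject_design: condition %s, seed %d, TR %g s\n",
              x$condition, x$seed, x$TR))
  for (r in x$runs)
    cat(sprintf("  run %d: %d events, %g s, %d volumes\n", r$run_index,
                nrow(r$events), r$total_duration, r$n_volumes))
  invisible(x)
}

#' Flatten a subject design into per-run event tables
#'
#' @param design A `subject_design`.
#' @return A list of three data frames (one per run) with columns
#'   `onset`, `duration`, `trial_type`, `stimulus_id`, `sequence`.
#' @export
design_to_events_table <- function(design) {
  stopifnot(inherits(design, "subject_design"))
  lapply(design$runs, function(r) {
    data.frame(onset = r$events$onset, duration = r$events$duration,
               trial_type = r$events$trial_type,
               stimulus_id = r$events$stimulus_id,
               sequence = r$events$sequence_index,
               stringsAsFactors = FALSE)
  })
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with a header line; round trips losslessly.
#'
#' @param events Data frame as produced by [design_to_events_table()].
#' @param path File path.
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Count trials of each type in a subject design
#' @param design A `subject_design`.
#' @return Named integer vector over trial types.
#' @export
design_trial_counts <- function(design) {
  tt <- unlist(lapply(design$runs, function(r) r$events$trial_type))
  counts <- table(factor(tt, levels = .TRIAL_TYPES))
  stats::setNames(as.integer(counts), names(counts))
}
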