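# Scoring of the out-of-scanner 4-alternative forced-choice recognition
# tests: proportions correct, the binomial above-chance inclusion rule, and
# the remembered/forgotten labels consumed by trial extraction.

#' Score a subject's recognition records
#'
#' Items the participant reported as previously familiar are omitted before
#' any proportion is computed. Chance level derives from the alternative
#' count (4AFC: 0.25), never a hard-coded constant.
#'
#' @param records Data frame with `stimulus_id`, `test1_correct`,
#'   `test2_correct`, `reported_familiar` (logicals).
#' @return List: `n` (items retained), `n_correct1`, `prop1`,
#'   `n_correct_both`, `prop_both`, `n_familiar`.
#' @export
score_recognition <- function(records) {
  stopifnot(nrow(records) >= 1)
  kept <- records[!records$reported_familiar, , drop = FALSE]
  if (nrow(kept) == 0)
    stop_submvpa("all items reported familiar; nothing to score")
  both <- kept$test1_correct & kept$test2_correct
  list(n = nrow(kept),
       n_correct1 = sum(kept$test1_correct),
       prop1 = mean(kept$test1_correct),
       n_correct_both = sum(both),
       prop_both = mean(both),
       n_familiar = sum(records$reported_familiar))
}

#' Binomial above-chance inclusion test
#'
#' A subject is included when performance is above chance on the first test
#' *and* across both tests. `p1` is the one-sided upper tail of
#' Binomial(n, 1/n_alternatives) at the test-1 correct count. The two-test
#' criterion (`both_null = "consistency"`, default) tests the count of
#' items correct on *both* tests against Binomial(n, (1/n_alternatives)^2),
#' the chance of guessing the same item right twice;
#' `both_null = "marginal"` instead tests the test-2 correct count against
#' the 4AFC chance level.
#'
#' @param records Recognition records (see [score_recognition()]).
#' @param alpha Cutoff (default 0.05).
#' @param n_alternatives Response alternatives (4).
#' @param both_null Null for the two-test criterion.
#' @return List: `include`, `p1`, `p_both`.
#' @export
inclusion_test <- function(records, alpha = 0.05, n_alternatives = 4,
                           both_null = c("consistency", "marginal")) {
  both_null <- match.arg(both_null)
  s <- score_recognition(records)
  chance <- 1 / n_alternatives
  p1 <- stats::pbinom(s$n_correct1 - 1, s$n, chance, lower.tail = FALSE)
  p_both <- if (both_null == "consistency")
    stats::pbinom(s$n_correct_both - 1, s$n, chance^2, lower.tail = FALSE)
  else {
    kept <- records[!records$reported_familiar, , drop = FALSE]
    stats::pbinom(sum(kept$test2_correct) - 1, s$n, chance,
                  lower.tail = FALSE)
  }
  list(include = p1 < alpha && p_both < alpha, p1 = p1, p_both = p_both)
}

#' Subsequent-memory labels from recognition records
#'
#' An item is `remembered` iff it was correct on the designated test
#' (first test by default); familiar-flagged items are dropped.
#'
#' @param records Recognition records.
#' @param which_test `"test1"` or `"test2"`.
#' @return Data frame `stimulus_id`, `true_label`.
#' @export
labels_from_behavior <- function(records, which_test = c("test1", "test2")) {
  which_test <- match.arg(which_test)
  kept <- records[!records$reported_familiar, , drop = FALSE]
  correct <- kept[[paste0(which_test, "_correct")]]
  data.frame(stimulus_id = kept$stimulus_id,
             true_label = ifelse(correct, "remembered", "forgotten"),
             stringsAsFactors = FALSE)
}

#' Simulate recognition records
#'
#' Generative model: each item is truly remembered with probability
#' `p_remember`; a remembered item is answered correctly, a forgotten item
#' is guessed correctly with probability `1/n_alternatives`. A remembered
#' item stays remembered at the second test with probability `p_retain`.
#' Setting `p_remember = 0` yields a pure chance-level guesser.
#'
#' @param n Items (62 novel stimuli by default).
#' @param p_remember True memory probability per item.
#' @param p_retain Retention probability between the two tests.
#' @param p_familiar Probability an item is reported previously familiar.
#' @param n_alternatives Response alternatives (4).
#' @param seed Integer seed.
#' @return Recognition records data frame.
#' @export
simulate_recognition_records <- function(n = 62, p_remember = 0.3,
                                         p_retain = 0.8, p_familiar = 0.01,
                                         n_alternatives = 4, seed = 1L) {
  with_seed(seed, {
    guess <- 1 / n_alternatives
    mem1 <- stats::runif(n) < p_remember
    mem2 <- mem1 & stats::runif(n) < p_retain
    data.frame(
      stimulus_id = sprintf("novel_%03d", seq_len(n)),
      test1_correct = mem1 | stats::runif(n) < guess,
      test2_correct = mem2 | stats::runif(n) < guess,
      reported_familiar = stats::runif(n) < p_familiar,
      stringsAsFactors = FALSE)
  })
}
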