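# Dataset-wise label-permutation inference for classifier accuracy: labels
# are shuffled over the whole dataset, but only training samples are
# actually relabeled in each fold; test folds keep their original labels.

#' Permutation test for cross-validated decoding accuracy
#'
#' Builds a null distribution by repeating the full nested
#' selection + classification pipeline on permuted labels. Each permutation
#' shuffles the label vector across the dataset (optionally within runs),
#' trains every fold on the permuted labels, and scores predictions against
#' the *original* test labels. The p-value uses the add-one Monte-Carlo
#' estimator `p = (1 + #{perm >= observed}) / (1 + n_permutations)`, which
#' is never exactly zero.
#'
#' @param ss A `sample_set` (typically counterbalanced).
#' @param plan A `fold_plan`.
#' @param k,C Passed to [cross_validate()].
#' @param n_permutations Number of permutations. `NULL` picks the scheme
#'   default: 10000 for `leave_one_run_out` (within subject), 1000 for
#'   `leave_one_subject_out` (cross subject). Reduced counts (e.g. 200)
#'   are supported for desk-scale runs.
#' @param seed Integer seed for the permutation stream.
#' @param stratify_by_run Shuffle labels within run (default `TRUE` for the
#'   within-subject scheme, preserving run-level class balance; `FALSE`
#'   gives the plain dataset-wise shuffle used cross-subject).
#' @param observed Optional precomputed `decoding_result` for the
#'   unpermuted data (recomputed when `NULL`).
#' @return A `permutation_null`: `observed_accuracy`,
#'   `permuted_accuracies`, `n_permutations`, `p_value`.
#' @export
permutation_test <- function(ss, plan, k = 100L, C = 1,
                             n_permutations = NULL, seed = 1L,
                             stratify_by_run =
                               plan$scheme == "leave_one_run_out",
                             observed = NULL) {
  stopifnot(inherits(ss, "sample_set"), inherits(plan, "fold_plan"))
  if (is.null(n_permutations))
    n_permutations <- if (plan$scheme == "leave_one_run_out") 10000L
                      else 1000L
  if (n_permutations < 1) stop_submvpa("n_permutations must be >= 1")
  if (is.null(observed))
    observed <- cross_validate(ss, plan, k = k, C = C)
  strata <- if (stratify_by_run) paste(ss$subject, ss$run)
            else rep("all", n_samples(ss))
  perm_acc <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    lab <- ss$labels
    for (g in unique(strata)) {
      idx <- which(strata == g)
      lab[idx] <- lab[sample(idx)]
    }
    .cross_validate_mat(ss$X, lab, plan, k = k, C = C,
                        test_labels = ss$labels)$mean_accuracy
  }, numeric(1)))
  p <- (1 + sum(perm_acc >= observed$mean_accuracy)) / (1 + n_permutations)
  structure(list(observed_accuracy = observed$mean_accuracy,
                 permuted_accuracies = perm_acc,
                 n_permutations = n_permutations, p_value = p),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null: observed %.3f, null mean %.3f, p = %.4g (%d perms)\n",
    x$observed_accuracy, mean(x$permuted_accuracies), x$p_value,
    x$n_permutations))
  invisible(x)
}
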