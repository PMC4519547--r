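# Two-class subsequent-memory decoding: linear soft-margin SVM on the 100
# voxels with the largest two-group ANOVA F, with selection recomputed
# inside every training fold (never on test data).

#' Two-group ANOVA F statistic per voxel
#'
#' One-way F for remembered vs forgotten, `F = MS_between / MS_within` with
#' df (1, n - 2), computed column-wise. Voxels with zero within-group
#' variance get `Inf` (always selected) and are flagged in the
#' `zero_within_variance` attribute. For two groups F equals the squared
#' pooled-variance t statistic.
#'
#' @param X Samples x voxels matrix.
#' @param labels Two-level factor/character, >= 2 samples per class.
#' @return Numeric vector of F values, one per column of `X`.
#' @export
anova_f_per_voxel <- function(X, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2 || any(table(labels) < 2))
    stop_submvpa("anova_f_per_voxel needs two classes with >= 2 samples each")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((X[g1, , drop = FALSE] -
                    rep(m1, each = n1))^2) +
         colSums((X[!g1, , drop = FALSE] -
                    rep(m2, each = n2))^2)
  f <- ifelse(ssw == 0, Inf, ssb / (ssw / (n - 2)))
  if (any(ssw == 0)) attr(f, "zero_within_variance") <- which(ssw == 0)
  f
}

#' Select the k voxels with the largest F values
#'
#' Ties are broken deterministically by the lowest voxel index. `k` larger
#' than the number of voxels is clamped with a warning (relevant for small
#' region masks).
#'
#' @param f Numeric F vector.
#' @param k Number of voxels to keep (default 100).
#' @return Sorted integer indices of the selected voxels.
#' @export
select_top_k <- function(f, k = 100L) {
  if (k < 1) stop_submvpa("k must be >= 1")
  if (k > length(f)) {
    warning("k = ", k, " exceeds ", length(f), " voxels; clamped")
    k <- length(f)
  }
  sort(order(-f, seq_along(f))[seq_len(k)])
}

#' Fit a linear soft-margin SVM
#'
#' Max-margin linear decision function `sign(w . x + b)` with fixed
#' regularization (default `C = 1`, not tuned). Features are used as given
#' (no internal rescaling); inputs are already z-scored upstream.
#'
#' @param X Training matrix (samples x selected voxels).
#' @param labels Two-level labels.
#' @param C Soft-margin cost.
#' @return A `linear_svm` with `weights`, `bias` and the fitted backend
#'   model; classify with [predict()].
#' @export
fit_linear_classifier <- function(X, labels, C = 1) {
  labels <- factor(as.character(labels),
                   levels = c("forgotten", "remembered"))
  if (nlevels(droplevels(labels)) < 2)
    stop_submvpa("training data must contain both classes")
  fit <- e1071::svm(x = X, y = labels, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  structure(list(model = fit, weights = w, bias = -fit$rho, C = C),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  factor(as.character(stats::predict(object$model, newdata)),
         levels = c("forgotten", "remembered"))
}

#' Build a cross-validation fold plan
#'
#' `leave_one_run_out` groups by run within a subject (3 runs give the
#' 3-fold scheme); `leave_one_subject_out` groups by subject for pooled
#' cross-subject data.
#'
#' @param ss A `sample_set`.
#' @param scheme Fold grouping scheme.
#' @return A `fold_plan`: list of folds with `train` / `test` row indices.
#' @export
make_fold_plan <- function(ss,
                           scheme = c("leave_one_run_out",
                                      "leave_one_subject_out")) {
  scheme <- match.arg(scheme)
  group <- if (scheme == "leave_one_run_out")
    paste(ss$subject, ss$run) else ss$subject
  folds <- lapply(unique(group), function(g)
    list(train = which(group != g), test = which(group == g)))
  structure(list(folds = folds, scheme = scheme), class = "fold_plan")
}

#' Confusion matrix with remembered as the positive class
#' @param predicted,actual Factors over forgotten/remembered.
#' @return A `confusion_matrix` (tp, fp, fn, tn).
#' @export
confusion_matrix <- function(predicted, actual) {
  structure(list(
    tp = sum(predicted == "remembered" & actual == "remembered"),
    fp = sum(predicted == "remembered" & actual == "forgotten"),
    fn = sum(predicted == "forgotten" & actual == "remembered"),
    tn = sum(predicted == "forgotten" & actual == "forgotten")),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("remembered", "forgotten"),
                              predicted = c("remembered", "forgotten")))
  print(m)
  cat(sprintf("precision %.3f, F-score %.3f, accuracy %.3f\n",
              precision(x), f_score(x), accuracy(x)))
  invisible(x)
}

#' Precision (true-positive accuracy): tp / (tp + fp)
#' @param cm A `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
precision <- function(cm) {
  if (cm$tp + cm$fp == 0)
    stop_submvpa("precision undefined: no positive predictions")
  cm$tp / (cm$tp + cm$fp)
}

#' F-score: 2 tp / (2 tp + fp + fn)
#' @param cm A `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
f_score <- function(cm) {
  den <- 2 * cm$tp + cm$fp + cm$fn
  if (den == 0) stop_submvpa("F-score undefined: denominator zero")
  2 * cm$tp / den
}

#' Accuracy from a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn)
}

#' Cross-validated decoding with nested feature selection
#'
#' In every fold the ANOVA-F scoring and top-k selection are recomputed on
#' the training portion only, an SVM is fitted on the selected voxels, and
#' the held-out samples are scored. `nested = FALSE` deliberately performs
#' selection on all samples (training + test) — a leakage diagnostic used
#' to demonstrate the optimistic bias that nesting prevents; never use it
#' for inference.
#'
#' @param ss A `sample_set`.
#' @param plan A `fold_plan`.
#' @param k Voxels retained by feature selection (clamped to the voxel
#'   count). `Inf` or `NULL` disables selection.
#' @param C SVM cost.
#' @param nested Keep feature selection inside training folds.
#' @return A `decoding_result`: `fold_accuracy`, `mean_accuracy` (unweighted
#'   mean over folds), `pooled_accuracy` (from the pooled confusion matrix),
#'   `confusion`, `scheme`, `feature_k`.
#' @export
cross_validate <- function(ss, plan, k = 100L, C = 1, nested = TRUE) {
  stopifnot(inherits(ss, "sample_set"), inherits(plan, "fold_plan"))
  .cross_validate_mat(ss$X, ss$labels, plan, k = k, C = C, nested = nested)
}

# matrix-level core shared by decode, permute and searchlight
.cross_validate_mat <- function(X, labels, plan, k = 100L, C = 1,
                                nested = TRUE, test_labels = labels) {
  fold_acc <- numeric(length(plan$folds))
  pred_all <- actual_all <- character(0)
  sel_global <- NULL
  if (!nested && !is.null(k) && is.finite(k)) {
    f <- anova_f_per_voxel(X, labels)
    sel_global <- suppressWarnings(select_top_k(f, k))
  }
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    if (length(fold$test) == 0) stop_submvpa("fold with empty test set")
    if (is.null(k) || !is.finite(k)) {
      sel <- seq_len(ncol(X))
    } else if (nested) {
      f <- anova_f_per_voxel(X[fold$train, , drop = FALSE],
                             labels[fold$train])
      sel <- suppressWarnings(select_top_k(f, k))
    } else sel <- sel_global
    model <- fit_linear_classifier(X[fold$train, sel, drop = FALSE],
                                   labels[fold$train], C = C)
    pred <- predict(model, X[fold$test, sel, drop = FALSE])
    truth <- test_labels[fold$test]
    fold_acc[i] <- mean(pred == truth)
    pred_all <- c(pred_all, as.character(pred))
    actual_all <- c(actual_all, as.character(truth))
  }
  cm <- confusion_matrix(factor(pred_all, c("forgotten", "remembered")),
                         factor(actual_all, c("forgotten", "remembered")))
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = accuracy(cm), confusion = cm,
                 scheme = plan$scheme,
                 feature_k = if (is.null(k)) NA_integer_ else k),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding_result (%s, k = %s): mean accuracy %.3f over %d folds\n",
    x$scheme, x$feature_k, x$mean_accuracy, length(x$fold_accuracy)))
  invisible(x)
}

#' Within-subject decoding averaged across subjects
#'
#' Runs leave-one-run-out cross-validation per subject and reports the mean
#' of the per-subject mean accuracies (each subject contributes one value,
#' whatever its sample count).
#'
#' @param sets List of per-subject `sample_set` objects.
#' @param k,C Passed to [cross_validate()].
#' @return List with `per_subject` (named accuracies), `mean_accuracy`,
#'   and `results` (per-subject `decoding_result`s).
#' @export
decode_within_subjects <- function(sets, k = 100L, C = 1) {
  res <- lapply(sets, function(ss)
    cross_validate(ss, make_fold_plan(ss, "leave_one_run_out"), k = k, C = C))
  acc <- vapply(res, `[[`, 0, "mean_accuracy")
  names(acc) <- vapply(sets, function(s) s$subject[1], "")
  list(per_subject = acc, mean_accuracy = mean(acc), results = res)
}
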