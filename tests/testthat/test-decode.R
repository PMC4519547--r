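test_that("two-group ANOVA F matches hand computation and the t-squared identity", {
  f <- anova_f_per_voxel(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                         rep(c("a", "b"), each = 3))
  expect_equal(unname(f), 13.5)
  # identical class means, nonzero spread -> F = 0
  f0 <- anova_f_per_voxel(matrix(c(1, 3, 1, 3), ncol = 1),
                          c("a", "a", "b", "b"))
  expect_equal(unname(f0), 0)
  # F == pooled t^2 across random datasets
  set.seed(10)
  for (i in 1:25) {
    X <- matrix(rnorm(24 * 4), 24, 4)
    lab <- rep(c("forgotten", "remembered"), each = 12)
    f <- anova_f_per_voxel(X, lab)
    t2 <- vapply(1:4, function(j)
      unname(t.test(X[lab == "forgotten", j], X[lab == "remembered", j],
                    var.equal = TRUE)$statistic^2), numeric(1))
    expect_equal(unname(f), t2, tolerance = 1e-10)
  }
  # zero within-variance -> Inf sentinel, flagged
  Xz <- cbind(rep(c(0, 1), each = 3), rnorm(6))
  fz <- anova_f_per_voxel(Xz, rep(c("a", "b"), each = 3))
  expect_equal(unname(fz[1]), Inf)
  expect_equal(attr(fz, "zero_within_variance"), 1L)
  expect_error(anova_f_per_voxel(Xz, rep("a", 6)), "two classes")
})

test_that("top-k selection is deterministic with index tie-breaking", {
  expect_equal(select_top_k(c(5, 4, 3, 2, 1), 3), 1:3)
  expect_equal(select_top_k(rep(1, 10), 5), 1:5)       # ties -> lowest index
  expect_equal(select_top_k(c(1, Inf, 2, Inf), 2), c(2L, 4L))
  expect_equal(select_top_k(rnorm(100), 100), 1:100)
  expect_warning(sel <- select_top_k(c(3, 1, 2), 7), "clamped")
  expect_equal(sel, 1:3)
  expect_error(select_top_k(1:3, 0), "k must be")
})

test_that("linear SVM behaves like a max-margin classifier", {
  X <- rbind(c(-1, 0), c(1, 0))
  lab <- c("forgotten", "remembered")
  m <- fit_linear_classifier(X, lab)
  expect_equal(as.character(predict(m, X)), lab)
  # flipping training labels flips every decision
  m2 <- fit_linear_classifier(X, rev(lab))
  pts <- matrix(rnorm(20), 10, 2)
  expect_true(all(predict(m, pts) != predict(m2, pts)))
  # duplicating the training set leaves the boundary unchanged (separable)
  set.seed(2)
  Xs <- rbind(matrix(rnorm(30, -2), 10, 3), matrix(rnorm(30, 2), 10, 3))
  labs <- rep(c("forgotten", "remembered"), each = 10)
  w1 <- fit_linear_classifier(Xs, labs)$weights
  w2 <- fit_linear_classifier(rbind(Xs, Xs), c(labs, labs))$weights
  expect_equal(w1 / sqrt(sum(w1^2)), w2 / sqrt(sum(w2^2)),
               tolerance = 1e-8)
  expect_error(fit_linear_classifier(X, c("remembered", "remembered")),
               "both classes")
})

test_that("fold plans partition samples by run or subject", {
  ss <- null_sample_set(n_per_run = 6, n_vox = 5, runs = 3)
  plan <- make_fold_plan(ss, "leave_one_run_out")
  expect_equal(length(plan$folds), 3L)
  tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(tested, seq_len(18))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(length(unique(ss$run[f$test])), 1L)
  }
  pooled <- combine_sample_sets(list(
    null_sample_set(4, 5, seed = 1, subject = "sub-01"),
    null_sample_set(4, 5, seed = 2, subject = "sub-02")))
  plan2 <- make_fold_plan(pooled, "leave_one_subject_out")
  expect_equal(length(plan2$folds), 2L)
  expect_equal(unique(pooled$subject[plan2$folds[[1]]$test]), "sub-01")
})

test_that("cross-validation recovers oracle features and stays at chance on noise", {
  orc <- oracle_sample_set(n_per_run = 10, n_vox = 20, seed = 1)
  plan <- make_fold_plan(orc, "leave_one_run_out")
  res <- cross_validate(orc, plan, k = 5)
  expect_equal(res$mean_accuracy, 1)
  expect_equal(accuracy(res$confusion), 1)
  # null accuracy near 0.5 over ~200 trials
  nulls <- lapply(1:4, function(i)
    null_sample_set(n_per_run = 18, n_vox = 40, seed = 40 + i,
                    subject = sprintf("sub-%02d", i)))
  accs <- vapply(nulls, function(ss)
    cross_validate(ss, make_fold_plan(ss, "leave_one_run_out"),
                   k = 10)$mean_accuracy, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("pooled confusion accuracy equals the sample-weighted fold mean", {
  ss <- null_sample_set(n_per_run = 10, n_vox = 30, seed = 5)
  # unequal fold sizes: drop some samples from run 0
  ss <- subset_samples(ss, 5:30)
  plan <- make_fold_plan(ss, "leave_one_run_out")
  res <- cross_validate(ss, plan, k = 8)
  sizes <- vapply(plan$folds, function(f) length(f$test), 0L)
  expect_equal(res$pooled_accuracy,
               sum(res$fold_accuracy * sizes) / sum(sizes))
  cm <- res$confusion
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, nrow(ss$X))
})

test_that("raising k from 100 to 500 barely moves null accuracy", {
  diffs <- vapply(1:4, function(i) {
    ss <- null_sample_set(n_per_run = 20, n_vox = 600, seed = 16 + i)
    plan <- make_fold_plan(ss, "leave_one_run_out")
    cross_validate(ss, plan, k = 500)$mean_accuracy -
      cross_validate(ss, plan, k = 100)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("confusion metrics reproduce the reported FM/EE values", {
  fm <- structure(list(tp = 161, fp = 113, fn = 119, tn = 167),
                  class = "confusion_matrix")
  ee <- structure(list(tp = 173, fp = 136, fn = 134, tn = 171),
                  class = "confusion_matrix")
  expect_equal(round(precision(fm), 2), 0.59)
  expect_equal(round(f_score(fm), 2), 0.58)
  expect_equal(round(precision(ee), 2), 0.56)
  expect_equal(round(f_score(ee), 2), 0.56)
  perfect <- structure(list(tp = 10, fp = 0, fn = 0, tn = 10),
                       class = "confusion_matrix")
  expect_equal(precision(perfect), 1)
  expect_equal(f_score(perfect), 1)
  none <- structure(list(tp = 0, fp = 0, fn = 5, tn = 5),
                    class = "confusion_matrix")
  expect_error(precision(none), "undefined")
  expect_error(f_score(structure(list(tp = 0, fp = 0, fn = 0, tn = 4),
                                 class = "confusion_matrix")), "undefined")
})

test_that("within-subject summary averages per-subject accuracies first", {
  sets <- list(oracle_sample_set(8, 15, seed = 1),
               null_sample_set(8, 15, seed = 2, subject = "sub-02"))
  sets[[1]]$subject[] <- "sub-01"
  res <- decode_within_subjects(sets, k = 5)
  expect_length(res$per_subject, 2)
  expect_equal(res$mean_accuracy, mean(res$per_subject))
  expect_equal(unname(res$per_subject[1]), 1)
})
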