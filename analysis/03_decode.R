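#!/usr/bin/env Rscript
# Whole-brain subsequent-memory decoding: nested ANOVA-F top-100 feature
# selection + linear SVM under (i) within-subject leave-one-run-out and
# (ii) cross-subject leave-one-subject-out cross-validation, with
# confusion-matrix metrics (precision / F-score, positive class =
# remembered).

source("analysis/00_common.R")

cat("== 03: whole-brain decoding ==\n")
sets <- simulate_cohort()

within <- decode_within_subjects(sets, k = 100)
cat(sprintf("Within-subject accuracy (mean of %d subjects): %.3f\n",
            length(sets), within$mean_accuracy))

pooled <- combine_sample_sets(sets)
plan <- make_fold_plan(pooled, "leave_one_subject_out")
cross <- cross_validate(pooled, plan, k = 100)
cat(sprintf("Cross-subject accuracy (mean of %d folds): %.3f\n",
            length(cross$fold_accuracy), cross$mean_accuracy))

write_tsv(rbind(
  data.frame(scheme = "within_subject", unit = names(within$per_subject),
             accuracy = unname(within$per_subject)),
  data.frame(scheme = "cross_subject",
             unit = sprintf("fold_%d", seq_along(cross$fold_accuracy)),
             accuracy = cross$fold_accuracy)), "decoding_results.tsv")

cm <- cross$confusion
cat(sprintf("Pooled cross-subject confusion: tp=%d fp=%d fn=%d tn=%d\n",
            cm$tp, cm$fp, cm$fn, cm$tn))
cat(sprintf("precision %.2f, F-score %.2f\n", precision(cm), f_score(cm)))
write_tsv(data.frame(scheme = "cross_subject", tp = cm$tp, fp = cm$fp,
                     fn = cm$fn, tn = cm$tn,
                     precision = precision(cm), f_score = f_score(cm),
                     accuracy = accuracy(cm)), "confusion.tsv")
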