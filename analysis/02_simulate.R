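#!/usr/bin/env Rscript
# Simulate the BOLD cohort: 6 fast-mapping subjects on a 16 x 16 x 8 grid,
# a stable class pattern (peak amplitude 1 noise-SD) confined to the
# ATL-like region, AR(1) noise plus slow drift. Volumes are written in a
# BIDS-like layout under scratch/ (bulky); the trial/label summary goes to
# results/.

source("analysis/00_common.R")

cat("== 02: BOLD simulation ==\n")
rows <- list()
for (i in seq_len(N_SUBJECTS)) {
  cfg <- cohort_config()
  cfg$seed <- MASTER_SEED + i
  sub <- simulate_subject("FM", cfg, subject_id = sprintf("sub-%02d", i))
  write_subject(sub, "scratch/sim")
  rows[[i]] <- data.frame(
    subject = sub$subject_id,
    n_novel = nrow(sub$truth),
    n_remembered = sum(sub$truth$true_label == "remembered"),
    prop_remembered = mean(sub$truth$true_label == "remembered"),
    n_volumes = sum(vapply(sub$volumes, function(v) dim(v$data)[4], 0L)))
}
summary <- do.call(rbind, rows)
print(summary, row.names = FALSE)
write_tsv(summary, "simulation_summary.tsv")
cat(sprintf(
  "Cohort mean remembered rate %.3f (generator default 0.3528 for FM).\n",
  mean(summary$prop_remembered)))
cat("Volumes under scratch/sim/sub-*/func/.\n")
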