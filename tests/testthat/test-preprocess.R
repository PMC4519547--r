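# direct constructor for hand-built volume series
vs_from_array <- function(arr, TR = 2, run_index = 0L) {
  structure(list(data = arr, TR = TR, affine = diag(4),
                 run_index = run_index, subject_id = "sub-01"),
            class = "volume_series")
}

test_that("baseline volume indices match an event-by-event enumeration", {
  d <- make_subject_design("FM", 13)
  for (r in 1:3) {
    rd <- d$runs[[r]]
    got <- baseline_volume_indices(rd)
    # oracle: loop over baseline events and acquisition times
    times <- (seq_len(rd$n_volumes) - 1) * rd$TR
    expected <- sort(unique(unlist(lapply(
      rd$events$onset[rd$events$trial_type == "baseline"], function(o)
        which(times >= o + 6 & times <= o + 8)))))
    expect_identical(got, expected)
    expect_true(all(got >= rd$lead_in / rd$TR + 1))  # lead-in excluded
    expect_true(all(got <= rd$n_volumes))
    expect_gte(length(got), 2)
  }
})

test_that("detrending removes a known linear drift", {
  nt <- 100L
  set.seed(8)
  base <- rnorm(nt)
  arr <- array(0, c(2, 1, 1, nt))
  arr[1, 1, 1, ] <- 5 + 0.37 * seq_len(nt) + base
  arr[2, 1, 1, ] <- 2 - 0.12 * seq_len(nt) + base
  out <- detrend_and_zscore(vs_from_array(arr), baseline_idx = 1:20)
  for (v in 1:2) {
    slope <- coef(lm(out$data[v, 1, 1, ] ~ seq_len(nt)))[2]
    expect_lt(abs(slope), 1e-8)
  }
})

test_that("baseline z-scoring yields mean 0 / SD 1 on baseline volumes", {
  set.seed(5)
  arr <- array(rnorm(4 * 50, mean = 100, sd = 7), c(2, 2, 1, 50))
  bidx <- c(5, 12, 20, 33, 41)
  out <- detrend_and_zscore(vs_from_array(arr), bidx, detrend = FALSE)
  B <- matrix(out$data, 4, 50)[, bidx]
  expect_equal(rowMeans(B), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(B, 1, sd), rep(1, 4), tolerance = 1e-10)
  # idempotent on already-normalized baseline statistics
  out2 <- detrend_and_zscore(out, bidx, detrend = FALSE)
  expect_equal(matrix(out2$data, 4, 50)[, bidx], B, tolerance = 1e-8)
})

test_that("zero-variance voxels are zeroed and flagged", {
  arr <- array(3, c(1, 1, 1, 10))
  out <- detrend_and_zscore(vs_from_array(arr), 1:5, detrend = FALSE)
  expect_true(all(out$data == 0))
  expect_equal(attr(out, "zero_variance_voxels"), 1L)
  expect_error(detrend_and_zscore(vs_from_array(arr), 3),
               "at least 2 baseline")
})

test_that("peak-window extraction picks and averages the right volumes", {
  nt <- 20L
  arr <- array(rep(0:(nt - 1), each = 4), c(2, 2, 1, nt))  # value = time/TR
  events <- data.frame(onset = c(12, 0), duration = 9,
                       trial_type = "novel_target",
                       stimulus_id = c("novel_001", "novel_002"),
                       sequence = 0)
  truth <- data.frame(stimulus_id = c("novel_001", "novel_002"),
                      true_label = c("remembered", "forgotten"))
  ss <- extract_trial_samples(vs_from_array(arr), events, truth)
  # onset 12: times 18, 20 -> volumes 10, 11 (1-based), values 9, 10
  expect_equal(unname(ss$X[1, 1]), 9.5)
  # onset 0: times 6, 8 -> values 3, 4
  expect_equal(unname(ss$X[2, 1]), 3.5)
  expect_equal(as.character(ss$labels), c("remembered", "forgotten"))
  # concatenate mode keeps the window volumes side by side
  sc <- extract_trial_samples(vs_from_array(arr), events, truth,
                              aggregate = "concatenate")
  expect_equal(ncol(sc$X), 8L)
  expect_equal(unname(sc$X[1, c(1, 5)]), c(9, 10))
})

test_that("trials whose window passes the run end are dropped, with warning", {
  arr <- array(rnorm(2 * 8), c(2, 1, 1, 8))  # run ends at 14 s
  events <- data.frame(onset = c(0, 10), duration = 9,
                       trial_type = "novel_target",
                       stimulus_id = c("novel_001", "novel_002"),
                       sequence = 0)
  truth <- data.frame(stimulus_id = events$stimulus_id,
                      true_label = c("remembered", "forgotten"))
  expect_warning(ss <- extract_trial_samples(vs_from_array(arr), events,
                                             truth),
                 "window exceeds run end")
  expect_equal(nrow(ss$X), 1L)
  expect_equal(ss$stimulus_id, "novel_001")
})

test_that("a full subject yields at most 62 trial samples", {
  sub <- tiny_subject(seed = 6, grid = c(4L, 4L, 2L))
  ss <- preprocess_subject(sub)
  expect_lte(nrow(ss$X), 62L)
  expect_equal(nrow(ss$X), 62L)  # no trial near run end in this design
  expect_equal(ncol(ss$X), 32L)
})

test_that("counterbalancing equalizes classes per run without fabrication", {
  ss <- null_sample_set(n_per_run = 16, n_vox = 10, seed = 3)
  # unbalance run 0: flip six forgotten to remembered
  idx <- which(ss$run == 0 & ss$labels == "forgotten")[1:6]
  ss$labels[idx] <- "remembered"
  cb <- counterbalance(ss, seed = 11)
  for (r in unique(cb$run)) {
    tab <- table(cb$labels[cb$run == r])
    expect_equal(unname(tab[1]), unname(tab[2]))
  }
  expect_true(all(cb$stimulus_id %in% ss$stimulus_id))  # subset, no fabrication
  expect_equal(sum(cb$run == 0), 4L)  # 2 forgotten remain -> 2 + 2
  # balanced runs unchanged; same seed -> identical selection
  expect_identical(counterbalance(ss, 11)$stimulus_id, cb$stimulus_id)
  bal <- null_sample_set(n_per_run = 8, n_vox = 5, seed = 4)
  expect_identical(counterbalance(bal, 1)$stimulus_id, bal$stimulus_id)
})

test_that("single-class runs are excluded with a warning", {
  ss <- null_sample_set(n_per_run = 8, n_vox = 5, seed = 9)
  ss$labels[ss$run == 1] <- "remembered"
  expect_warning(cb <- counterbalance(ss, 2), "single class")
  expect_false(1L %in% cb$run)
  expect_true(all(table(cb$labels, cb$run) > 0))
})
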