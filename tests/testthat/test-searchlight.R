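test_that("sphere offsets match brute-force lattice enumeration for radii 0-5", {
  for (r in 0:5) {
    off <- sphere_offsets(r)
    brute <- brute_force_ball(r)
    expect_equal(nrow(off), nrow(brute))
    expect_equal(off[order(off[, 1], off[, 2], off[, 3]), ],
                 brute[order(brute[, 1], brute[, 2], brute[, 3]), ],
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(2)), 33L)
  expect_equal(nrow(sphere_offsets(4)), 257L)
  expect_true(any(apply(sphere_offsets(3) == 0, 1, all)))  # center included
  # deterministic lexicographic order
  off <- sphere_offsets(2)
  expect_identical(off, off[order(off[, 1], off[, 2], off[, 3]), ])
  expect_error(sphere_offsets(-1), "radius")
})

test_that("searchlight localizes signal and clips at grid edges", {
  gd <- c(8L, 8L, 4L)
  region <- sphere_mask(gd, c(3, 3, 2), 1.5)
  sub <- tiny_subject(seed = 44, effect_size = 1.5, grid = gd,
                      regions = list(A = region))
  ss <- counterbalance(preprocess_subject(sub), 1)
  plan <- make_fold_plan(ss, "leave_one_run_out")
  map <- searchlight_map(ss, plan, radius = 1)
  # every center is computed, including grid corners (edge clipping)
  expect_false(any(is.nan(map$data)))
  expect_true(all(map$data >= 0 & map$data <= 1))
  # the accuracy peak lies inside the signal region dilated by the radius
  peak <- which(map$data == max(map$data), arr.ind = TRUE)[1, ]
  dilated <- sphere_mask(gd, c(3, 3, 2), 1.5 + 1)
  expect_true(dilated[peak[1], peak[2], peak[3]])
  # restricting the analysis mask restricts the computed centers
  am <- box_mask(gd, c(1, 1, 1), c(4, 8, 4))
  map2 <- searchlight_map(ss, plan, radius = 1, analysis_mask = am)
  expect_true(all(is.nan(map2$data[5:8, , ])))
  expect_equal(map2$data[1:4, , ], map$data[1:4, , ])
  expect_error(searchlight_map(ss, plan, radius = 0), "radius")
  expect_error(searchlight_map(ss, plan, radius = 1,
                               analysis_mask = array(FALSE, gd)), "empty")
})

test_that("maps at different radii are spatially correlated on the same signal", {
  gd <- c(8L, 8L, 4L)
  region <- sphere_mask(gd, c(4, 4, 2), 2)
  sub <- tiny_subject(seed = 45, effect_size = 1.5, grid = gd,
                      regions = list(A = region))
  ss <- counterbalance(preprocess_subject(sub), 1)
  plan <- make_fold_plan(ss, "leave_one_run_out")
  m1 <- searchlight_map(ss, plan, radius = 1)
  m2 <- searchlight_map(ss, plan, radius = 2)
  expect_gt(cor(as.numeric(m1$data), as.numeric(m2$data)), 0.3)
})

test_that("map values are invariant to sample order", {
  ss <- null_sample_set(n_per_run = 6, n_vox = 12, seed = 3)
  ss$voxel_index <- submvpa:::.grid_voxel_index(c(3L, 2L, 2L))
  ss$grid_dim <- c(3L, 2L, 2L)
  plan <- make_fold_plan(ss, "leave_one_run_out")
  m1 <- searchlight_map(ss, plan, radius = 1)
  perm <- submvpa:::with_seed(8, sample(nrow(ss$X)))
  ssp <- subset_samples(ss, perm)
  m2 <- searchlight_map(ssp, make_fold_plan(ssp, "leave_one_run_out"),
                        radius = 1)
  expect_equal(m1$data, m2$data)
})

test_that("binomial thresholding flags only above-chance centers", {
  gd <- c(4L, 4L, 2L)
  map <- structure(list(data = array(0.5, gd), n_test = 40,
                        radius = 1, grid_dim = gd, threshold = NULL,
                        significant = NULL), class = "accuracy_map")
  th <- threshold_map(map)
  expect_equal(sum(th$significant), 0L)
  map$data[2, 2, 1] <- 1
  th <- threshold_map(map)
  expect_true(th$significant[2, 2, 1])
  expect_equal(sum(th$significant), 1L)
  expect_equal(th$p_values[2, 2, 1], 2^-40, tolerance = 1e-6)
  # FDR correction never adds voxels
  th_fdr <- threshold_map(map, correction = "fdr")
  expect_lte(sum(th_fdr$significant), sum(th$significant))
})

test_that("false-positive rate of thresholding is near alpha on null maps", {
  # null accuracies drawn from the exact chance distribution per center
  gd <- c(6L, 6L, 4L)
  n <- 40
  rates <- vapply(1:6, function(i) {
    acc <- submvpa:::with_seed(500 + i,
                               array(rbinom(prod(gd), n, 0.5) / n, gd))
    map <- structure(list(data = acc, n_test = n, radius = 1,
                          grid_dim = gd, threshold = NULL,
                          significant = NULL), class = "accuracy_map")
    mean(threshold_map(map, alpha = 0.05)$significant)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})

test_that("peak reporting tabulates 6-connected clusters", {
  gd <- c(6L, 6L, 4L)
  map <- structure(list(data = array(NaN, gd), n_test = 40, radius = 1,
                        grid_dim = gd, threshold = 0.05,
                        significant = array(FALSE, gd)),
                   class = "accuracy_map")
  expect_equal(nrow(report_peaks(map)), 0L)
  # one 3-voxel line cluster, one isolated voxel with higher accuracy
  map$data[, , ] <- 0.5
  map$significant[2:4, 2, 1] <- TRUE
  map$data[2:4, 2, 1] <- c(0.7, 0.8, 0.75)
  map$significant[6, 6, 4] <- TRUE
  map$data[6, 6, 4] <- 0.95
  peaks <- report_peaks(map)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$size, c(1L, 3L))  # sorted by peak accuracy desc
  expect_equal(peaks$peak_accuracy, c(0.95, 0.8))
  # world coordinates via the default 3x3x5 mm affine, 0-based voxels
  expect_equal(unlist(peaks[2, c("x_mm", "y_mm", "z_mm")]),
               c(x_mm = (3 - 1) * 3, y_mm = (2 - 1) * 3, z_mm = 0))
  # a diagonal-only neighbor is NOT 6-connected
  map$significant[] <- FALSE
  map$significant[1, 1, 1] <- TRUE
  map$significant[2, 2, 1] <- TRUE
  map$data[] <- 0.8
  expect_equal(nrow(report_peaks(map)), 2L)
  expect_equal(nrow(report_peaks(map, min_cluster_size = 2)), 0L)
})
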