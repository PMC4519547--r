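# Spherical searchlight information mapping: for every voxel, classify on
# the features of its integer-lattice spherical neighborhood (no top-k
# selection inside the searchlight — the spatial projection is the
# selection) and record the cross-validated accuracy at the center.

#' Integer offsets of a spherical searchlight neighborhood
#'
#' All integer 3-vectors with Euclidean norm <= `radius`, in lexicographic
#' order. Radius is measured in voxel-index units on the grid: radius 4
#' yields the 257-voxel ball, radius 0 the center alone.
#'
#' @param radius Neighborhood radius in voxel units, >= 0.
#' @return Integer matrix `m x 3` of offsets, containing `(0, 0, 0)`.
#' @export
#' @examples
#' nrow(sphere_offsets(4))  # 257
sphere_offsets <- function(radius) {
  if (radius < 0) stop_submvpa("radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2
  m <- as.matrix(g[keep, c("dx", "dy", "dz")])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

#' Map cross-validated accuracy over spherical neighborhoods
#'
#' For every center voxel inside `analysis_mask`, features are projected
#' onto the (edge-clipped) neighborhood and [cross_validate()] is run with
#' no feature selection; the mean fold accuracy is written at the center.
#' Neighborhoods clipped below 2 voxels are left undefined (`NaN`), as are
#' voxels outside the mask. The result is independent of center order.
#'
#' @param ss A `sample_set` carrying full-grid features.
#' @param plan A `fold_plan`.
#' @param radius Neighborhood radius in voxel units (>= 1).
#' @param analysis_mask Optional 3D logical array of centers to evaluate;
#'   `NULL` evaluates every voxel of the sample set.
#' @param C SVM cost.
#' @return An `accuracy_map`: 3D `data` grid of accuracies, `n_test`
#'   (total test samples per center), `radius`, `grid_dim`.
#' @export
searchlight_map <- function(ss, plan, radius = 4, analysis_mask = NULL,
                            C = 1) {
  stopifnot(inherits(ss, "sample_set"), inherits(plan, "fold_plan"))
  if (radius < 1) stop_submvpa("searchlight radius must be >= 1")
  gd <- ss$grid_dim
  if (!is.null(analysis_mask)) {
    if (!identical(as.integer(dim(analysis_mask)), gd))
      stop_submvpa("analysis mask shape does not match the grid")
    if (!any(analysis_mask)) stop_submvpa("analysis mask is empty")
  }
  pos <- array(0L, gd)
  lin_feat <- ss$voxel_index[, 1] + (ss$voxel_index[, 2] - 1L) * gd[1] +
    (ss$voxel_index[, 3] - 1L) * gd[1] * gd[2]
  pos[lin_feat] <- seq_len(ncol(ss$X))
  centers <- ss$voxel_index
  if (!is.null(analysis_mask))
    centers <- centers[analysis_mask[centers], , drop = FALSE]
  off <- sphere_offsets(radius)
  acc <- array(NaN, gd)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] + off[, 1]
    cy <- centers[i, 2] + off[, 2]
    cz <- centers[i, 3] + off[, 3]
    ok <- cx >= 1L & cx <= gd[1] & cy >= 1L & cy <= gd[2] &
      cz >= 1L & cz <= gd[3]
    cols <- pos[cbind(cx[ok], cy[ok], cz[ok])]
    cols <- cols[cols > 0L]
    if (length(cols) < 2L) next
    res <- .cross_validate_mat(ss$X[, cols, drop = FALSE], ss$labels,
                               plan, k = NULL, C = C)
    acc[centers[i, 1], centers[i, 2], centers[i, 3]] <- res$mean_accuracy
  }
  structure(list(data = acc, n_test = n_samples(ss), radius = radius,
                 grid_dim = gd, threshold = NULL, significant = NULL),
            class = "accuracy_map")
}

#' Threshold an accuracy map for above-chance performance
#'
#' Per defined center, a one-sided exact binomial test of the implied
#' correct-classification count against Binomial(`n_test_samples`, 0.5);
#' centers with `p < alpha` are marked significant. Uncorrected by default
#' (the map is descriptive); `correction = "fdr"` applies
#' Benjamini-Hochberg across defined centers.
#'
#' @param map An `accuracy_map`.
#' @param n_test_samples Test samples contributing to each center's
#'   accuracy (defaults to the map's `n_test`).
#' @param alpha Significance level.
#' @param correction `"none"` or `"fdr"`.
#' @return The map with `threshold`, `p_values` and logical `significant`
#'   grid filled in.
#' @export
threshold_map <- function(map, n_test_samples = map$n_test, alpha = 0.05,
                          correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(inherits(map, "accuracy_map"), n_test_samples > 0)
  defined <- which(!is.nan(map$data))
  correct <- round(map$data[defined] * n_test_samples)
  p <- stats::pbinom(correct - 1, n_test_samples, 0.5, lower.tail = FALSE)
  if (correction == "fdr") p <- stats::p.adjust(p, "BH")
  pv <- array(NaN, dim(map$data))
  pv[defined] <- p
  sig <- array(FALSE, dim(map$data))
  sig[defined] <- p < alpha
  map$threshold <- alpha
  map$p_values <- pv
  map$significant <- sig
  map
}

# 6-connected components of a logical grid; returns integer label array
.connected_components <- function(mask) {
  gd <- dim(mask)
  labels <- array(0L, gd)
  cur <- 0L
  idx <- which(mask)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (gd[1] * gd[2])
      rem <- (v - 1L) %% (gd[1] * gd[2])
      coord <- c(rem %% gd[1] + 1L, rem %/% gd[1] + 1L, z + 1L)
      for (s in seq_len(6)) {
        nb <- coord + shifts[s, ]
        if (any(nb < 1) || any(nb > gd)) next
        nlin <- nb[1] + (nb[2] - 1L) * gd[1] + (nb[3] - 1L) * gd[1] * gd[2]
        if (mask[nlin] && labels[nlin] == 0L) {
          labels[nlin] <- cur
          queue <- c(queue, nlin)
        }
      }
    }
  }
  labels
}

#' Tabulate significant clusters and their accuracy peaks
#'
#' Connected components (6-connectivity) of the thresholded map's
#' significant grid, one row per cluster of at least `min_cluster_size`
#' voxels: size, peak accuracy, and the peak's world coordinates via the
#' affine. Rows are sorted by peak accuracy, descending.
#'
#' @param map A thresholded `accuracy_map` (see [threshold_map()]).
#' @param min_cluster_size Minimum voxels per reported cluster.
#' @param affine 4 x 4 voxel-to-world transform (0-based voxel indices);
#'   default scales by the 3 x 3 x 5 mm acquisition voxel size.
#' @return Data frame `cluster, size, peak_accuracy, x_mm, y_mm, z_mm`.
#' @export
report_peaks <- function(map, min_cluster_size = 1,
                         affine = diag(c(3, 3, 5, 1))) {
  stopifnot(inherits(map, "accuracy_map"))
  if (is.null(map$significant))
    stop_submvpa("map must be thresholded first (threshold_map)")
  labels <- .connected_components(map$significant)
  n_cl <- max(labels)
  rows <- list()
  for (cl in seq_len(n_cl)) {
    vox <- which(labels == cl, arr.ind = TRUE)
    if (nrow(vox) < min_cluster_size) next
    accs <- map$data[vox]
    peak <- vox[which.max(accs), ]
    world <- drop(affine %*% c(peak - 1, 1))[1:3]
    rows[[length(rows) + 1]] <- data.frame(
      size = nrow(vox), peak_accuracy = max(accs),
      x_mm = world[1], y_mm = world[2], z_mm = world[3])
  }
  if (length(rows) == 0)
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_accuracy = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_accuracy), , drop = FALSE]
  cbind(cluster = seq_len(nrow(out)), out, row.names = NULL)
}

#' Write an accuracy map (and significance mask) as NIfTI
#'
#' @param map An `accuracy_map`.
#' @param path Output path for the accuracy volume; if the map is
#'   thresholded, a `*_sig` volume is written alongside.
#' @return `path`, invisibly.
#' @export
write_accuracy_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$data), path)
  if (!is.null(map$significant)) {
    sig_path <- sub("(\\.nii(\\.gz)?)$", "_sig\\1", path)
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(map$significant),
                            dim(map$significant))), sig_path)
  }
  invisible(path)
}
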