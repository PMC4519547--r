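# Region-restricted decoding: run the identical pipeline on voxels inside a
# mask. Synthetic brains have no anatomy, so geometric mask generators
# (spheres, boxes) stand in for anatomical regions; real masks are NIfTI.

#' Geometric region masks
#'
#' `sphere_mask` marks voxels within `radius` (voxel units, Euclidean) of
#' `center`; `box_mask` marks an axis-aligned box. Both return 3D logical
#' arrays usable as informative regions or decoding ROIs.
#'
#' @param grid_dim Integer 3-vector grid shape.
#' @param center Integer 3-vector, 1-based voxel coordinates.
#' @param radius Sphere radius in voxel units.
#' @param lower,upper Inclusive 1-based corner coordinates of the box.
#' @return 3D logical array of shape `grid_dim`.
#' @export
sphere_mask <- function(grid_dim, center, radius) {
  g <- .grid_voxel_index(grid_dim)
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2
  array(d2 <= radius^2, grid_dim)
}

#' @rdname sphere_mask
#' @export
box_mask <- function(grid_dim, lower, upper) {
  g <- .grid_voxel_index(grid_dim)
  inside <- g[, 1] >= lower[1] & g[, 1] <= upper[1] &
    g[, 2] >= lower[2] & g[, 2] <= upper[2] &
    g[, 3] >= lower[3] & g[, 3] <= upper[3]
  array(inside, grid_dim)
}

#' Read / write a binary NIfTI mask
#'
#' Nonzero voxels are inside the region.
#'
#' @param path NIfTI-1 file path.
#' @param mask 3D logical array.
#' @return `read_mask_nifti` returns a 3D logical array.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.array(img) != 0, dim(img)[1:3])
}

#' @rdname read_mask_nifti
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))),
                     path)
  invisible(path)
}

#' Restrict a sample set to the voxels of a mask
#'
#' Features are sliced to mask-true coordinates; ordering (x-fastest grid
#' scan) is preserved.
#'
#' @param ss A `sample_set` carrying full-grid (or already restricted)
#'   features.
#' @param mask 3D logical array with the sample set's grid shape.
#' @return The restricted `sample_set`.
#' @export
apply_mask <- function(ss, mask) {
  stopifnot(inherits(ss, "sample_set"))
  if (!identical(as.integer(dim(mask)), ss$grid_dim))
    stop_submvpa("mask shape does not match the sample set grid")
  if (!any(mask)) stop_submvpa("mask selects no voxels")
  keep <- mask[ss$voxel_index]
  if (!any(keep))
    stop_submvpa("mask does not intersect the sample set's voxels")
  sample_set(ss$X[, keep, drop = FALSE], ss$labels, ss$run, ss$subject,
             ss$stimulus_id, ss$voxel_index[keep, , drop = FALSE],
             ss$grid_dim)
}

#' Decode within each of several regions (plus whole brain)
#'
#' Runs [cross_validate()] with the same fold plan for the unrestricted
#' sample set and for each mask, so regional accuracies are directly
#' comparable. `k` is clamped per region when a mask holds fewer voxels.
#'
#' @param ss A `sample_set` with full-grid features.
#' @param masks Named list of 3D logical arrays.
#' @param plan A `fold_plan` shared by all regions.
#' @param k,C Passed to [cross_validate()].
#' @return List with `table` (data frame: region, n_voxels, k_used, mean
#'   and pooled accuracy) and `results` (named `decoding_result`s,
#'   `whole_brain` first).
#' @export
roi_battery <- function(ss, masks, plan, k = 100L, C = 1) {
  stopifnot(length(masks) >= 1, !is.null(names(masks)))
  sets <- c(list(whole_brain = ss), lapply(masks, apply_mask, ss = ss))
  results <- lapply(sets, function(s) {
    kk <- min(k, ncol(s$X))
    cross_validate(s, plan, k = kk, C = C)
  })
  tab <- data.frame(
    region = names(sets),
    n_voxels = vapply(sets, function(s) ncol(s$X), 0L),
    k_used = vapply(results, function(r) as.integer(r$feature_k), 0L),
    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
    pooled_accuracy = vapply(results, `[[`, 0, "pooled_accuracy"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, results = results)
}
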