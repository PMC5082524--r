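# Probabilistic overlap maps and consistency statistics.

#' Build a probabilistic overlap map from binarised activation maps
#'
#' Voxel-wise sum of per-subject binary template-space maps: the value at
#' each voxel is the number of subjects with suprathreshold activation
#' there. By convention the inputs are the unsmoothed individual maps.
#'
#' @param maps List of logical 3-D arrays (or `binary_activation_map`s) on
#'   a common template grid.
#' @param n_total Total number of subjects in the cohort (>= length(maps)).
#' @return An `overlap_map`: `data` (integer array), `n_total`, `n_maps`.
#' @export
build_overlap_map <- function(maps, n_total = length(maps)) {
  stopifnot(length(maps) >= 1)
  arrs <- lapply(maps, function(m) {
    if (inherits(m, "binary_activation_map")) m$data else m
  })
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1)))) {
    stop("maps are not on a common grid", call. = FALSE)
  }
  acc <- array(0L, dim = d)
  for (a in arrs) acc <- acc + as.integer(a)
  if (max(acc) > n_total) {
    stop("overlap count exceeds n_total", call. = FALSE)
  }
  structure(list(data = acc, n_total = n_total, n_maps = length(maps)),
            class = "overlap_map")
}

#' Peak of an overlap map within an ROI
#'
#' The in-ROI voxel with the maximum subject count (ties broken by raster
#' order). The percentage is reported relative to the number of subjects
#' with significant in-ROI activation at that threshold, rounded to the
#' nearest integer (half away from zero).
#'
#' @param om An `overlap_map`.
#' @param roi Non-empty logical ROI mask.
#' @param n_active Number of subjects with >= 1 suprathreshold in-ROI voxel
#'   (> 0).
#' @param space Optional `template_space`; when given the peak world
#'   coordinate is included.
#' @return List with `count`, `pct_of_active`, `vox` (voxel index) and
#'   `mm` (world coordinate, or NULL).
#' @export
overlap_peak <- function(om, roi, n_active, space = NULL) {
  stopifnot(inherits(om, "overlap_map"))
  if (sum(roi) == 0) stop("empty ROI mask", call. = FALSE)
  if (n_active <= 0) stop("n_active must be > 0", call. = FALSE)
  roi_idx <- which(as.logical(roi))
  best <- roi_idx[which.max(om$data[roi_idx])]
  vox <- as.integer(arrayInd(best, dim(om$data)))
  count <- om$data[best]
  list(count = as.integer(count),
       pct_of_active = as.integer(round_half_up(100 * count / n_active)),
       vox = vox,
       mm = if (is.null(space)) NULL else vox_to_mm(space, as.numeric(vox)))
}

#' Euclidean distance between two template-space coordinates
#'
#' @param a_mm,b_mm Length-3 mm coordinates.
#' @return Distance in mm, reported to 0.1 mm.
#' @export
peak_distance <- function(a_mm, b_mm) {
  stopifnot(length(a_mm) == 3, length(b_mm) == 3)
  round(sqrt(sum((as.numeric(a_mm) - as.numeric(b_mm))^2)), 1)
}

#' Fraction of hippocampal peak records labelled anterior
#'
#' Applies the long-axis split (boundary counts anterior) to each record's
#' y coordinate and reports the anterior fraction as an integer percent.
#'
#' @param peaks A data.frame of peak records with a `y_mm` column.
#' @param y_split_mm Long-axis boundary in mm.
#' @return Integer percent of records labelled anterior.
#' @export
anterior_fraction <- function(peaks, y_split_mm) {
  if (is.null(nrow(peaks)) || nrow(peaks) == 0) {
    stop("no peak records supplied", call. = FALSE)
  }
  as.integer(round_half_up(100 * mean(peaks$y_mm >= y_split_mm)))
}

#' Number of voxel centres within a sphere
#'
#' Counts voxel centres whose Euclidean distance to `center_mm` is
#' <= `r_mm`. On a 2 mm isotropic grid a 5 mm sphere centred on a voxel
#' centre contains 81 voxels.
#'
#' @param space A `template_space`.
#' @param center_mm Sphere centre in mm (on the grid).
#' @param r_mm Radius in mm (>= 0).
#' @return Integer voxel count.
#' @export
voxels_within_radius <- function(space, center_mm, r_mm) {
  stopifnot(inherits(space, "template_space"), length(center_mm) == 3)
  if (r_mm < 0) stop("radius must be >= 0", call. = FALSE)
  dx2 <- (axis_coords(space, 1) - center_mm[1])^2
  dy2 <- (axis_coords(space, 2) - center_mm[2])^2
  dz2 <- (axis_coords(space, 3) - center_mm[3])^2
  sum(outer(outer(dx2, dy2, "+"), dz2, "+") <= r_mm^2)
}
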