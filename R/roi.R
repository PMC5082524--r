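# ROI transformation, thresholding, clustering and peak extraction.

# Nearest-neighbour resampling of a 3-D map (binary or continuous). For
# every output voxel the world coordinate is pushed through
# `out_mm_to_in_mm` and the nearest input voxel sampled (out-of-grid -> 0 /
# FALSE). Output and input share `space` geometry.
resample_nn <- function(vol, space, out_mm_to_in_mm) {
  d <- space$grid_shape
  vox <- arrayInd(seq_len(prod(d)), d)
  mm_out <- vox_to_mm(space, vox)
  mm_in <- cbind(mm_out, 1) %*% t(out_mm_to_in_mm)
  vin <- round(mm_to_vox(space, mm_in[, 1:3, drop = FALSE]))
  ok <- vin[, 1] >= 1 & vin[, 1] <= d[1] &
    vin[, 2] >= 1 & vin[, 2] <= d[2] &
    vin[, 3] >= 1 & vin[, 3] <= d[3]
  out <- array(if (is.logical(vol)) FALSE else 0, dim = d)
  lin <- vin[ok, 1] + (vin[ok, 2] - 1) * d[1] + (vin[ok, 3] - 1) * d[1] * d[2]
  out[which(ok)] <- vol[lin]
  out
}
resample_mask_nn <- function(mask, space, out_mm_to_in_mm) {
  resample_nn(mask == TRUE | mask > 0, space, out_mm_to_in_mm)
}

#' Transform a template-space ROI mask into subject space
#'
#' Nearest-neighbour resampling of the binary mask through the inverse of
#' the subject-to-template affine (the template-to-subject direction).
#'
#' @param mask Logical/0-1 3-D template-space mask.
#' @param affine_subject_to_template 4x4 affine (subject mm -> template mm);
#'   must be invertible.
#' @param space The shared `template_space` geometry.
#' @param roi_name Optional name used in the empty-result error.
#' @return Logical subject-space mask.
#' @export
to_subject_space <- function(mask, affine_subject_to_template, space,
                             roi_name = "ROI") {
  if (abs(det(affine_subject_to_template)) < 1e-12) {
    stop("singular affine", call. = FALSE)
  }
  out <- resample_mask_nn(mask, space, affine_subject_to_template)
  if (!any(out)) {
    stop(sprintf("ROI '%s' is empty after transformation to subject space",
                 roi_name), call. = FALSE)
  }
  out
}

#' Transform a subject-space binary map into template space
#'
#' Nearest-neighbour resampling through the subject-to-template affine
#' (sampling the subject map at the inverse-mapped template coordinates).
#' Empty results are allowed (a subject may have no suprathreshold voxels).
#'
#' @inheritParams to_subject_space
#' @param mask Subject-space map: logical/0-1 (resampled as a mask) or
#'   continuous (resampled as values).
#' @return Template-space map of the same type.
#' @export
map_to_template <- function(mask, affine_subject_to_template, space) {
  if (abs(det(affine_subject_to_template)) < 1e-12) {
    stop("singular affine", call. = FALSE)
  }
  if (is.logical(mask)) {
    resample_mask_nn(mask, space, solve(affine_subject_to_template))
  } else {
    resample_nn(mask, space, solve(affine_subject_to_template))
  }
}

#' Threshold / smoothing specification for individual-level maps
#'
#' @param z_threshold Voxel-wise Z cutoff (> 0); the conventional set is
#'   2.3, 3.1, 3.9.
#' @param fwhm Smoothing FWHM in mm the Z map was computed at (0, 2 or 5).
#' @return A `threshold_spec`.
#' @export
threshold_spec <- function(z_threshold, fwhm = 0) {
  stop_if_not_scalar_number(z_threshold, "z_threshold")
  if (z_threshold <= 0) stop("z_threshold must be > 0", call. = FALSE)
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  structure(list(z_threshold = z_threshold, fwhm = fwhm),
            class = "threshold_spec")
}

#' Binarise a Z map at a voxel-wise threshold
#'
#' Strict one-sided inclusion: a voxel enters the map iff Z > z_threshold.
#' The spec's smoothing level must match the map's recorded level.
#'
#' @param zmap A `zmap`.
#' @param spec A `threshold_spec`.
#' @return A `binary_activation_map`: list with logical `data`,
#'   `z_threshold`, `fwhm`, `contrast`, `space_tag`, `space`.
#' @export
threshold_zmap <- function(zmap, spec) {
  stopifnot(inherits(zmap, "zmap"), inherits(spec, "threshold_spec"))
  if (!isTRUE(all.equal(zmap$fwhm, spec$fwhm))) {
    stop(sprintf("smoothing mismatch: zmap fwhm %g, spec fwhm %g",
                 zmap$fwhm, spec$fwhm), call. = FALSE)
  }
  structure(list(data = zmap$data > spec$z_threshold,
                 z_threshold = spec$z_threshold, fwhm = spec$fwhm,
                 contrast = zmap$contrast, space_tag = zmap$space_tag,
                 space = zmap$space),
            class = "binary_activation_map")
}

# Neighbour offsets for a connectivity scheme (half-space, no duplicates).
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- switch(as.character(connectivity),
                "6" = rowSums(abs(g)) == 1,
                "18" = rowSums(abs(g)) <= 2,
                "26" = rep(TRUE, nrow(g)))
  g <- g[ord, , drop = FALSE]
  # keep one of each +/- pair
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
}

# Component labels for a set of voxel linear indices on a grid of shape d.
# Returns an integer label per index (1..n_components).
label_components_idx <- function(idx, d, connectivity = 26L) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  rank_arr <- integer(prod(d))
  rank_arr[idx] <- seq_len(n)
  coords <- arrayInd(idx, d)
  offs <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nb1 <- coords[, 1] + offs[j, 1]
    nb2 <- coords[, 2] + offs[j, 2]
    nb3 <- coords[, 3] + offs[j, 3]
    ok <- nb1 >= 1 & nb1 <= d[1] & nb2 >= 1 & nb2 <= d[2] &
      nb3 >= 1 & nb3 <= d[3]
    lin <- nb1[ok] + (nb2[ok] - 1L) * d[1] + (nb3[ok] - 1L) * d[1] * d[2]
    r <- rank_arr[lin]
    hit <- r > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, r[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  as.integer(igraph::components(g)$membership)
}

# Component labels for the suprathreshold voxels of a binary 3-D array.
# Returns list(idx = linear indices, labels = component id per index).
label_components <- function(binary, connectivity = 26L) {
  idx <- which(binary)
  list(idx = idx,
       labels = label_components_idx(idx, dim(binary), connectivity))
}

#' Connected-component clusters of a binary activation map
#'
#' Components under 6-, 18- or 26-neighbour connectivity (default 26, the
#' FSL cluster convention). When `values` is supplied, each cluster's peak
#' voxel is the in-cluster maximum (ties broken by raster order: x fastest,
#' then y, then z).
#'
#' @param binary A `binary_activation_map` or logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @param values Optional numeric array (e.g. the Z map) for peak voxels.
#' @return A `cluster_set`: `labels` (integer array, 0 = background),
#'   `sizes` (voxel count per cluster), `peaks` (matrix of peak voxel
#'   indices, one row per cluster), `n_clusters`.
#' @export
find_clusters <- function(binary, connectivity = 26L, values = NULL) {
  arr <- if (inherits(binary, "binary_activation_map")) binary$data else binary
  stopifnot(length(dim(arr)) == 3)
  lab <- label_components(arr, connectivity)
  labels <- array(0L, dim = dim(arr))
  if (length(lab$idx)) labels[lab$idx] <- lab$labels
  n_clusters <- if (length(lab$labels)) max(lab$labels) else 0L
  sizes <- if (n_clusters) tabulate(lab$labels, nbins = n_clusters) else integer(0)
  peaks <- NULL
  if (n_clusters) {
    peaks <- matrix(NA_integer_, n_clusters, 3)
    for (cl in seq_len(n_clusters)) {
      members <- lab$idx[lab$labels == cl]
      best <- if (is.null(values)) min(members) else {
        v <- values[members]
        members[which.max(v)]   # first max in linear (raster) order
      }
      peaks[cl, ] <- arrayInd(best, dim(arr))
    }
  }
  structure(list(labels = labels, sizes = sizes, peaks = peaks,
                 n_clusters = n_clusters, connectivity = connectivity),
            class = "cluster_set")
}

#' Does an ROI contain suprathreshold activation?
#'
#' @param zmap A `zmap`.
#' @param roi Logical ROI mask on the same grid/space.
#' @param spec A `threshold_spec` (its fwhm must match the map's).
#' @param roi_space_tag Space tag of the ROI; must match the map's.
#' @return List with `active` (TRUE iff >= 1 suprathreshold voxel inside
#'   the ROI) and `n_voxels` (the in-ROI suprathreshold count).
#' @export
roi_has_activation <- function(zmap, roi, spec,
                               roi_space_tag = zmap$space_tag) {
  stopifnot(inherits(zmap, "zmap"))
  if (!identical(roi_space_tag, zmap$space_tag)) {
    stop(sprintf("space mismatch: zmap is '%s', roi is '%s'",
                 zmap$space_tag, roi_space_tag), call. = FALSE)
  }
  if (sum(roi) == 0) stop("empty ROI mask", call. = FALSE)
  if (!identical(dim(zmap$data), dim(roi))) {
    stop("zmap and roi grids differ", call. = FALSE)
  }
  bin <- threshold_zmap(zmap, spec)
  n <- sum(bin$data & as.logical(roi))
  list(active = n >= 1L, n_voxels = as.integer(n))
}

#' Peak voxel of a Z map within an ROI
#'
#' The in-ROI voxel with maximal Z; ties are broken deterministically by
#' the smallest linear index in raster order (x fastest, then y, then z).
#' The coordinate is reported as the voxel centre in world mm. A peak below
#' a supplied threshold is allowed and flagged (`suprathreshold = FALSE`).
#'
#' @param zmap A `zmap` with a known `space`.
#' @param roi Non-empty logical ROI mask.
#' @param z_threshold Optional threshold used only to set the
#'   `suprathreshold` flag.
#' @param subject_id,roi_name Metadata copied into the record.
#' @param hc_split_y_mm Optional y boundary; when given, the record carries
#'   an anterior/posterior `long_axis` label.
#' @return A one-row data.frame (`peak_record`): subject, roi, contrast,
#'   x_mm, y_mm, z_mm, peak_z, hemisphere ("L"/"R"), suprathreshold,
#'   long_axis.
#' @export
peak_in_roi <- function(zmap, roi, z_threshold = NULL, subject_id = NA,
                        roi_name = NA_character_, hc_split_y_mm = NULL) {
  stopifnot(inherits(zmap, "zmap"))
  roi_idx <- which(as.logical(roi))
  if (!length(roi_idx)) stop("empty ROI mask", call. = FALSE)
  v <- zmap$data[roi_idx]
  best <- roi_idx[which.max(v)]   # which.max takes the first (raster) max
  vox <- arrayInd(best, dim(zmap$data))
  mm <- vox_to_mm(zmap$space, as.numeric(vox))
  peak_z <- zmap$data[best]
  long_axis <- NA_character_
  if (!is.null(hc_split_y_mm)) {
    long_axis <- if (mm[2] >= hc_split_y_mm) "anterior" else "posterior"
  }
  data.frame(subject = subject_id, roi = roi_name, contrast = zmap$contrast,
             x_mm = mm[1], y_mm = mm[2], z_mm = mm[3], peak_z = peak_z,
             hemisphere = if (mm[1] >= 0) "R" else "L",
             suprathreshold = if (is.null(z_threshold)) NA else
               peak_z > z_threshold,
             long_axis = long_axis, stringsAsFactors = FALSE)
}

#' Label a hippocampal coordinate anterior or posterior
#'
#' Anterior iff y >= `y_split_mm` (the boundary itself counts as anterior).
#'
#' @param peak_mm Length-3 mm coordinate.
#' @param y_split_mm Long-axis boundary (mm); conventionally -21, the
#'   uncal-apex level.
#' @param hc_mask,space Optional mask and space; when supplied the
#'   coordinate must fall inside the mask.
#' @return `"anterior"` or `"posterior"`.
#' @export
split_hc_long_axis <- function(peak_mm, y_split_mm, hc_mask = NULL,
                               space = NULL) {
  stopifnot(length(peak_mm) == 3)
  if (!is.null(hc_mask)) {
    stopifnot(!is.null(space))
    vox <- round(mm_to_vox(space, peak_mm))
    d <- dim(hc_mask)
    inside <- all(vox >= 1) && all(vox <= d) &&
      as.logical(hc_mask[vox[1], vox[2], vox[3]])
    if (!inside) stop("coordinate lies outside the HC mask", call. = FALSE)
  }
  if (peak_mm[2] >= y_split_mm) "anterior" else "posterior"
}
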