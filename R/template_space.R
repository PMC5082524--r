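#' Define a template voxel grid
#'
#' A desk-scale stand-in for a standard isotropic template space. World
#' coordinates are in mm; voxel (1,1,1) sits at `origin_mm`, and the default
#' origin centres the grid so that coordinates span negative and positive
#' values along every axis, mimicking template-style mm coordinates.
#'
#' @param grid_shape Integer vector of length 3: voxels per axis (x, y, z).
#' @param voxel_size Isotropic voxel edge length in mm (default 2).
#' @param origin_mm World coordinate of voxel (1,1,1); defaults to
#'   `-voxel_size * floor(grid_shape / 2)`.
#' @return An object of class `template_space` with fields `grid_shape`,
#'   `voxel_size`, `origin_mm` and the voxel-to-mm `affine` (4x4, voxel
#'   indices 1-based).
#' @examples
#' sp <- template_space()
#' vox_to_mm(sp, c(1, 1, 1))
#' @export
template_space <- function(grid_shape = c(40L, 48L, 40L), voxel_size = 2,
                           origin_mm = NULL) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  stop_if_not_scalar_number(voxel_size, "voxel_size")
  if (voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (is.null(origin_mm)) {
    origin_mm <- -voxel_size * floor(grid_shape / 2)
  }
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_size
  # voxel index i (1-based) maps to origin + (i - 1) * voxel_size
  affine[1:3, 4] <- origin_mm - voxel_size
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         origin_mm = as.numeric(origin_mm), affine = affine),
    class = "template_space"
  )
}

#' @export
print.template_space <- function(x, ...) {
  cat(sprintf("<template_space> %d x %d x %d voxels @ %g mm, origin (%g, %g, %g) mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size, x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Convert voxel indices to world mm coordinates
#'
#' @param space A `template_space`.
#' @param vox Numeric vector of length 3 or an n x 3 matrix of 1-based voxel
#'   indices.
#' @return Coordinates of the voxel centres in world mm (same shape).
#' @export
vox_to_mm <- function(space, vox) {
  stopifnot(inherits(space, "template_space"))
  v <- if (is.matrix(vox)) vox else matrix(vox, ncol = 3)
  out <- sweep(v - 1, 2, space$origin_mm / space$voxel_size, "+") * space$voxel_size
  if (is.matrix(vox)) out else as.numeric(out)
}

#' Convert world mm coordinates to (fractional) voxel indices
#'
#' @param space A `template_space`.
#' @param mm Numeric vector of length 3 or an n x 3 matrix of mm coordinates.
#' @return 1-based voxel indices, possibly fractional.
#' @export
mm_to_vox <- function(space, mm) {
  stopifnot(inherits(space, "template_space"))
  m <- if (is.matrix(mm)) mm else matrix(mm, ncol = 3)
  out <- sweep(m, 2, space$origin_mm, "-") / space$voxel_size + 1
  if (is.matrix(mm)) out else as.numeric(out)
}

# mm coordinates of every voxel centre along one axis.
axis_coords <- function(space, axis) {
  space$origin_mm[axis] + (seq_len(space$grid_shape[axis]) - 1) * space$voxel_size
}

# Fixed template-space ROI geometry (mm). Spheres for PHG/RSC/TOS and a
# tube along y for the hippocampus so it admits an anterior/posterior split.
# Bilateral: every region is mirrored in x. Coordinates are chosen to fit
# grids down to 30 x 36 x 30 voxels at 2 mm.
.roi_geometry <- list(
  PHG = list(kind = "sphere", center = c(18, -16, -8), radius = 5),
  RSC = list(kind = "sphere", center = c(10, -30, 12), radius = 4),
  TOS = list(kind = "sphere", center = c(24, -32, 18), radius = 4),
  HC  = list(kind = "tube", x = 24, z = -16, y_range = c(-28, -4),
             radius = 3.5)
)

#' Consensus scene-effect centres per ROI
#'
#' World-mm coordinates (right hemisphere) used as the cohort-level consensus
#' location of the planted scene effect in each region.
#'
#' @return Named list of length-3 mm coordinates for PHG, RSC, TOS, HC.
#' @export
roi_consensus_centers <- function() {
  list(PHG = c(18, -16, -8), RSC = c(10, -30, 12),
       TOS = c(24, -32, 18), HC = c(24, -12, -16))
}

#' Build the four anatomical ROI masks in template space
#'
#' Constructs disjoint, bilaterally mirrored binary masks for the
#' parahippocampal gyrus (PHG), retrosplenial cortex (RSC), transverse
#' occipital sulcus (TOS) and hippocampus (HC) at fixed template
#' coordinates. The HC mask is elongated along y so that it has voxels on
#' both sides of the anterior/posterior boundary `hc_split_y_mm`.
#'
#' @param space A `template_space`; must be large enough to hold all four
#'   regions (>= roughly 30 x 36 x 30 voxels at 2 mm).
#' @param hc_split_y_mm Anterior/posterior hippocampal boundary in mm
#'   (default -21, the conventional uncal-apex level).
#' @return An object of class `roi_set`: list with `masks` (named list of
#'   logical 3-D arrays), `hc_split_y_mm` and `space`.
#' @export
make_template_rois <- function(space = template_space(), hc_split_y_mm = -21) {
  stopifnot(inherits(space, "template_space"))
  stop_if_not_scalar_number(hc_split_y_mm, "hc_split_y_mm")
  xs <- axis_coords(space, 1)
  ys <- axis_coords(space, 2)
  zs <- axis_coords(space, 3)

  mask_for <- function(g) {
    m <- array(FALSE, dim = space$grid_shape)
    if (g$kind == "sphere") {
      for (sgn in c(1, -1)) {
        ctr <- g$center * c(sgn, 1, 1)
        dx2 <- (xs - ctr[1])^2
        dy2 <- (ys - ctr[2])^2
        dz2 <- (zs - ctr[3])^2
        m <- m | (outer(outer(dx2, dy2, "+"), dz2, "+") <= g$radius^2)
      }
    } else {
      iy <- ys >= g$y_range[1] & ys <= g$y_range[2]
      for (sgn in c(1, -1)) {
        dx2 <- (xs - sgn * g$x)^2
        dz2 <- (zs - g$z)^2
        disk <- outer(dx2, dz2, "+") <= g$radius^2   # x-z cross-section
        tube <- aperm(outer(disk, iy, "&"), c(1, 3, 2))
        m <- m | tube
      }
    }
    m
  }

  masks <- lapply(.roi_geometry, mask_for)
  names(masks) <- names(.roi_geometry)

  counts <- vapply(masks, sum, numeric(1))
  if (any(counts == 0)) {
    stop("grid too small: empty ROI mask(s): ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(total > 1L)) {
    stop("grid too small: ROI masks overlap after voxelisation", call. = FALSE)
  }
  hc_y <- ys[apply(masks$HC, 2, any)]
  if (!any(hc_y >= hc_split_y_mm) || !any(hc_y < hc_split_y_mm)) {
    stop("HC mask does not straddle hc_split_y_mm", call. = FALSE)
  }
  structure(list(masks = masks, hc_split_y_mm = hc_split_y_mm, space = space),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", paste(sprintf("%s=%d", names(x$masks),
                                 vapply(x$masks, sum, numeric(1))),
                         collapse = " "),
      sprintf("voxels; HC split at y = %g mm\n", x$hc_split_y_mm))
  invisible(x)
}
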