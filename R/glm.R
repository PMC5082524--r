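#' Fit the voxel-wise GLM by ordinary least squares
#'
#' Per-voxel OLS of the BOLD series on the (already high-passed) design.
#' Residual variance is SSR / dof with dof = n_volumes - rank(X).
#'
#' @param bold A `bold_volume`, or a numeric matrix (time x voxels).
#' @param design A `design_matrix` (its `X` is used), or a numeric matrix.
#' @param mask Optional logical array / index vector restricting the fit to
#'   a voxel subset (the returned maps are zero-filled elsewhere).
#' @return A `glm_fit`: `betas` (columns x voxels), `sigma2`, `dof`,
#'   `xtx_inv`, `design`, `voxels` (fitted linear indices), `grid_shape`,
#'   `space`, `space_tag`.
#' @export
fit_glm <- function(bold, design, mask = NULL) {
  Y <- if (inherits(bold, "bold_volume")) bold$data else as.matrix(bold)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (nrow(Y) != nrow(X)) {
    stop("BOLD series length does not match design rows", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  voxels <- if (is.null(mask)) seq_len(ncol(Y)) else {
    if (is.logical(mask) || is.array(mask)) which(as.logical(mask)) else as.integer(mask)
  }
  # columns may already correspond to the masked voxel set
  Ys <- if (length(voxels) == ncol(Y)) Y else Y[, voxels, drop = FALSE]
  xtx_inv <- chol2inv(chol(crossprod(X)))
  betas <- xtx_inv %*% crossprod(X, Ys)
  rownames(betas) <- colnames(X)
  dof <- nrow(X) - ncol(X)
  resid <- Ys - X %*% betas
  sigma2 <- colSums(resid^2) / dof
  # exact fits leave only floating-point residue: treat as zero variance
  scale <- colMeans(Ys^2)
  sigma2[sigma2 <= 1e-20 * pmax(scale, .Machine$double.xmin)] <- 0
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 xtx_inv = xtx_inv, design = design, voxels = voxels,
                 grid_shape = if (inherits(bold, "bold_volume"))
                   bold$space$grid_shape else NULL,
                 space = if (inherits(bold, "bold_volume")) bold$space else NULL,
                 space_tag = "subject"),
            class = "glm_fit")
}

#' Contrast weight vectors over the design columns
#'
#' @param name One of `"scenes>scrambled"`, `"scenes>objects"`,
#'   `"objects>scrambled"`, `"objects>scenes"`.
#' @param columns Design column labels (default the standard four).
#' @return A `contrast_spec`: list with `name` and `weights`.
#' @export
contrast_spec <- function(name,
                          columns = c("scenes", "objects", "scrambled",
                                      "constant")) {
  parts <- strsplit(name, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% columns) ||
      parts[1] == parts[2]) {
    stop(sprintf("unknown contrast '%s'", name), call. = FALSE)
  }
  w <- numeric(length(columns))
  names(w) <- columns
  w[parts[1]] <- 1
  w[parts[2]] <- -1
  w["constant"] <- 0
  if (all(w == 0)) stop("contrast weights are all zero", call. = FALSE)
  structure(list(name = name, weights = w), class = "contrast_spec")
}

#' Convert t statistics to standard-normal Z
#'
#' Matched-quantile mapping through the t tail probability, computed in
#' log-tail space so large statistics (|t| up to ~40) map to finite Z
#' without underflow.
#'
#' @param t Numeric t values.
#' @param dof Residual degrees of freedom.
#' @return Z values of the same sign and tail probability.
#' @export
t_to_z <- function(t, dof) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t != 0
  logp <- stats::pt(abs(t[pos]), df = dof, lower.tail = FALSE, log.p = TRUE)
  z[pos] <- sign(t[pos]) *
    stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' Voxel-wise contrast Z map
#'
#' t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c), converted to Z by matched
#' log-tail quantile mapping. Zero-variance voxels yield Z = 0 when the
#' contrast value is 0, and are capped at +/- `z_cap` otherwise.
#'
#' @param fit A `glm_fit`.
#' @param contrast A `contrast_spec` or contrast name string.
#' @param fwhm_mm Smoothing level (mm) recorded in the map metadata
#'   (default 0); never inferred from the data.
#' @param z_cap Cap for zero-variance non-zero-contrast voxels (default 8.2).
#' @return A `zmap`: list with `data` (3-D array when the grid is known,
#'   else a vector), `contrast`, `fwhm`, `space_tag`, `space`, `voxels`.
#' @export
contrast_zmap <- function(fit, contrast, fwhm_mm = 0, z_cap = 8.2) {
  stopifnot(inherits(fit, "glm_fit"))
  cs <- if (inherits(contrast, "contrast_spec")) contrast else contrast_spec(contrast)
  labels <- rownames(fit$betas)
  if (!all(names(cs$weights) %in% labels)) {
    stop("contrast is not compatible with the fitted design", call. = FALSE)
  }
  w <- numeric(length(labels))
  names(w) <- labels
  w[names(cs$weights)] <- cs$weights
  if (all(w == 0)) stop("contrast weights are all zero", call. = FALSE)
  cb <- as.numeric(w %*% fit$betas)
  cvc <- as.numeric(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(fit$sigma2 * cvc)
  t <- ifelse(se > 0, cb / se, 0)
  z <- t_to_z(t, fit$dof)
  # zero-variance voxels: Z = 0 when the contrast is (numerically) zero,
  # capped otherwise (exact fits of a real effect)
  bscale <- sqrt(colSums(fit$betas^2))
  genuine <- se == 0 & abs(cb) > 1e-10 * bscale
  z[genuine] <- sign(cb[genuine]) * z_cap
  if (!is.null(fit$grid_shape)) {
    data <- array(0, dim = fit$grid_shape)
    data[fit$voxels] <- z
  } else {
    data <- z
  }
  structure(list(data = data, contrast = cs$name, fwhm = fwhm_mm,
                 space_tag = fit$space_tag, space = fit$space,
                 voxels = fit$voxels),
            class = "zmap")
}

#' Separable Gaussian smoothing of a 3-D map
#'
#' Convolution with an isotropic Gaussian kernel of the stated FWHM,
#' applied separably along each axis with zero padding at the boundary.
#' `fwhm_mm = 0` is the identity.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  stopifnot(length(dim(vol)) == 3)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  for (axis in 1:3) {
    vol <- conv_along_axis(vol, k, axis)
  }
  vol
}

# 1-D zero-padded convolution along one axis of a 3-D array, via a banded
# matrix multiply (kernel length is small relative to the axis).
conv_along_axis <- function(vol, k, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- K %*% matrix(v, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Percent signal change for a condition within an ROI
#'
#' PSC = 100 * (beta_condition - beta_scrambled) * regressor_height /
#' baseline_mean, averaged over ROI voxels. The regressor height is the
#' peak-to-peak amplitude of the HRF-convolved condition regressor (the
#' conventional scaling used when reporting localiser percent signal
#' change), and the baseline is the mean fitted constant over the ROI
#' unless supplied.
#'
#' @param fit A `glm_fit` whose design carries `heights`.
#' @param condition `"scenes"` or `"objects"`.
#' @param roi Logical ROI mask (same grid as the fit).
#' @param regressor_height Peak-to-peak regressor height; default taken
#'   from the fit's design metadata.
#' @param baseline_mean Baseline intensity; default mean constant beta over
#'   the ROI. Must be > 0.
#' @return Scalar percent signal change.
#' @export
percent_signal_change <- function(fit, condition, roi,
                                  regressor_height = NULL,
                                  baseline_mean = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!condition %in% rownames(fit$betas)) {
    stop(sprintf("condition '%s' not in design", condition), call. = FALSE)
  }
  roi_idx <- which(as.logical(roi))
  sel <- match(roi_idx, fit$voxels)
  sel <- sel[!is.na(sel)]
  if (!length(sel)) stop("ROI contains no fitted voxels", call. = FALSE)
  if (is.null(regressor_height)) {
    h <- fit$design$heights
    if (is.null(h)) stop("regressor_height not supplied and not in design",
                         call. = FALSE)
    regressor_height <- h[[condition]]
  }
  if (is.null(baseline_mean)) {
    baseline_mean <- mean(fit$betas["constant", sel])
  }
  if (baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
  eff <- fit$betas[condition, sel] - fit$betas["scrambled", sel]
  mean(100 * eff * regressor_height / baseline_mean)
}
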