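# Shared fixtures, built in code at test time.

# Small template grid that still fits all four ROIs.
small_space <- function() template_space(c(30L, 36L, 30L))

# Tiny grid for resampling / clustering unit tests (no ROIs needed).
tiny_space <- function(n = 8L) template_space(c(n, n, n))

# Standard schedule and design, built once per test run.
std_schedule <- build_block_schedule()
std_design <- build_design_matrix(std_schedule)

# Wrap a 3-D array as a zmap on `space`.
as_zmap <- function(arr, space, contrast = "scenes>objects", fwhm = 0,
                    space_tag = "subject") {
  structure(list(data = arr, contrast = contrast, fwhm = fwhm,
                 space_tag = space_tag, space = space,
                 voxels = seq_along(arr)),
            class = "zmap")
}

# Brute-force OLS via the normal equations (independent of fit_glm).
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  list(beta = as.numeric(beta), sigma2 = sum(res^2) / dof,
       xtx_inv = xtx_inv, dof = dof)
}

# First-level fit of one synthetic subject restricted to its ROI voxels.
fit_subject_rois <- function(subject, design = std_design, sigma_s = 50) {
  m <- Reduce(`|`, subject$roi_masks)
  Yf <- highpass(subject$bold$data[, which(m), drop = FALSE],
                 sigma_s = sigma_s, TR_s = subject$bold$TR_s)
  fb <- structure(list(data = Yf, space = subject$bold$space,
                       TR_s = subject$bold$TR_s,
                       n_volumes = subject$bold$n_volumes,
                       affine_subject_to_template =
                         subject$bold$affine_subject_to_template),
                  class = "bold_volume")
  fit_glm(fb, design, mask = which(m))
}

# Noise-free single-subject spec with a planted scene effect.
noiseless_spec <- function(space = small_space(), amplitude = 2,
                           object_amplitude = 0, n_subjects = 1,
                           base_seed = 5) {
  cohort_spec(n_subjects = n_subjects, base_seed = base_seed, space = space,
              rois = make_template_rois(space),
              amplitude_mean_pct = amplitude, amplitude_sd_pct = 0,
              object_amplitude_mean_pct = object_amplitude,
              object_amplitude_sd_pct = 0,
              jitter_sd_mm = 0, noise_sd = 0, drift_amplitude = 0,
              max_shift_mm = 0)
}
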