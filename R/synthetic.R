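#' Specify a synthetic localiser cohort
#'
#' Bundles the template space, ROI set and effect/noise distribution
#' parameters for a multi-subject synthetic BOLD cohort. Defaults emulate
#' the study conditions the analyses assume: a 51-subject cohort, TR 3 s,
#' 214 volumes (40 x 16 s blocks, post-discard), a ~3% scene effect against
#' a weaker object effect, 4 mm inter-subject jitter of effect centres,
#' white noise at 5% of baseline and a mild slow drift.
#'
#' @param n_subjects Number of subjects (default 51).
#' @param base_seed Base RNG seed; subject i uses `base_seed + i`.
#' @param space A `template_space`.
#' @param rois A `roi_set` (default [make_template_rois()] on `space`).
#' @param amplitude_mean_pct,amplitude_sd_pct Mean/SD of the per-subject
#'   scene effect amplitude, percent of baseline (default 3, 1).
#' @param object_amplitude_mean_pct,object_amplitude_sd_pct Same for the
#'   object effect (default 1.5, 0.5). Amplitudes are truncated at 0.
#' @param jitter_sd_mm SD of the isotropic Gaussian jitter applied to each
#'   subject's effect centre around the consensus location (default 4 mm).
#' @param noise_sd SD of the additive white Gaussian noise, in intensity
#'   units (default 50 = 5% of the 1000-unit baseline).
#' @param drift_amplitude Amplitude scale of the 128-s cosine drift, in
#'   intensity units (default 10 = 1% of baseline).
#' @param baseline Baseline intensity (default 1000).
#' @param max_shift_mm Maximum rigid head-position offset per axis; subject
#'   affines are whole-voxel translations drawn uniformly within this bound
#'   (default 4 mm).
#' @param effect_fwhm_mm FWHM of the Gaussian effect blob (default 8 mm).
#' @param TR_s Repetition time (default 3 s).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 51L, base_seed = 1L,
                        space = template_space(),
                        rois = make_template_rois(space),
                        amplitude_mean_pct = 3, amplitude_sd_pct = 1,
                        object_amplitude_mean_pct = 1.5,
                        object_amplitude_sd_pct = 0.5,
                        jitter_sd_mm = 4, noise_sd = 50,
                        drift_amplitude = 10, baseline = 1000,
                        max_shift_mm = 4, effect_fwhm_mm = 8, TR_s = 3) {
  stopifnot(n_subjects >= 1,
            amplitude_sd_pct >= 0, object_amplitude_sd_pct >= 0,
            jitter_sd_mm >= 0, noise_sd >= 0, drift_amplitude >= 0,
            baseline > 0, max_shift_mm >= 0, effect_fwhm_mm > 0)
  stopifnot(inherits(space, "template_space"), inherits(rois, "roi_set"))
  structure(list(
    n_subjects = as.integer(n_subjects), base_seed = as.integer(base_seed),
    space = space, rois = rois,
    amplitude_mean_pct = amplitude_mean_pct,
    amplitude_sd_pct = amplitude_sd_pct,
    object_amplitude_mean_pct = object_amplitude_mean_pct,
    object_amplitude_sd_pct = object_amplitude_sd_pct,
    jitter_sd_mm = jitter_sd_mm, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, baseline = baseline,
    max_shift_mm = max_shift_mm, effect_fwhm_mm = effect_fwhm_mm,
    TR_s = TR_s), class = "cohort_spec")
}

#' Sample a subject's effect centre around the consensus location
#'
#' Draws an isotropic Gaussian offset from the consensus coordinate, then
#' clamps the result to the centre of the nearest in-ROI voxel. With zero
#' jitter the consensus coordinate is returned exactly.
#'
#' @param consensus_mm Consensus centre (mm), inside `roi`.
#' @param jitter_sd_mm Gaussian jitter SD in mm (>= 0).
#' @param roi Logical 3-D ROI mask.
#' @param space The `template_space` of `roi`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Length-3 mm coordinate of an in-ROI voxel centre (or the
#'   consensus itself when `jitter_sd_mm = 0`).
#' @export
sample_subject_center <- function(consensus_mm, jitter_sd_mm, roi, space, seed) {
  if (sum(roi) == 0) stop("empty ROI mask", call. = FALSE)
  stopifnot(jitter_sd_mm >= 0)
  if (jitter_sd_mm == 0) return(as.numeric(consensus_mm))
  target <- consensus_mm + with_seed(seed, stats::rnorm(3, 0, jitter_sd_mm))
  vox <- arrayInd(which(roi), dim(roi))
  mm <- vox_to_mm(space, vox)
  d2 <- rowSums(sweep(mm, 2, target, "-")^2)
  as.numeric(mm[which.min(d2), ])
}

#' Ground-truth record for one synthetic subject
#'
#' @param subject_id Integer id.
#' @param center_mm Named list of per-ROI planted scene-effect centres
#'   (template-space mm).
#' @param amplitude_pct Scene effect amplitude, percent of baseline (>= 0).
#' @param object_amplitude_pct Object effect amplitude, percent of baseline.
#' @param jitter_sd_mm Jitter SD used when sampling the centres.
#' @param noise_sd,drift_amplitude,baseline Noise model parameters.
#' @param affine_subject_to_template 4x4 affine mapping subject mm to
#'   template mm (must be invertible).
#' @return A `subject_truth` object.
#' @export
subject_truth <- function(subject_id, center_mm, amplitude_pct,
                          object_amplitude_pct, jitter_sd_mm, noise_sd,
                          drift_amplitude, baseline = 1000,
                          affine_subject_to_template = diag(4)) {
  stopifnot(amplitude_pct >= 0, object_amplitude_pct >= 0)
  if (abs(det(affine_subject_to_template)) < 1e-12) {
    stop("affine_subject_to_template is not invertible", call. = FALSE)
  }
  structure(list(subject_id = subject_id, center_mm = center_mm,
                 amplitude_pct = amplitude_pct,
                 object_amplitude_pct = object_amplitude_pct,
                 jitter_sd_mm = jitter_sd_mm, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, baseline = baseline,
                 affine_subject_to_template = affine_subject_to_template),
            class = "subject_truth")
}

# Gaussian effect blob (unit peak) at `center_mm`, truncated at 3 sigma.
# Returned as a sparse pair (voxel linear indices, weights).
effect_blob <- function(space, center_mm, fwhm_mm) {
  sigma <- fwhm_to_sigma(fwhm_mm)
  r <- 3 * sigma
  xs <- axis_coords(space, 1); ys <- axis_coords(space, 2)
  zs <- axis_coords(space, 3)
  ix <- which(abs(xs - center_mm[1]) <= r)
  iy <- which(abs(ys - center_mm[2]) <= r)
  iz <- which(abs(zs - center_mm[3]) <= r)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(list(idx = integer(0), w = numeric(0)))
  }
  g <- expand.grid(x = ix, y = iy, z = iz)
  d2 <- (xs[g$x] - center_mm[1])^2 + (ys[g$y] - center_mm[2])^2 +
    (zs[g$z] - center_mm[3])^2
  keep <- d2 <= r^2
  idx <- (g$x + (g$y - 1L) * space$grid_shape[1] +
            (g$z - 1L) * prod(space$grid_shape[1:2]))[keep]
  list(idx = as.integer(idx), w = exp(-d2[keep] / (2 * sigma^2)))
}

#' Generate one subject's 4-D BOLD series
#'
#' The signal model is
#' `baseline * (1 + sum_c effect_map_c * regressor_c(t)) + drift + noise`:
#' each condition's effect map is a Gaussian blob (FWHM `effect_fwhm_mm`,
#' truncated at 3 sigma) of peak amplitude `amplitude_pct / 100` at the
#' subject's planted centre (scenes) or `object_amplitude_pct / 100`
#' (objects); regressors are the HRF-convolved boxcars scaled to unit
#' peak-to-peak so the planted percentage is recovered on the
#' percent-signal-change scale. Drift is a 128-s cosine with per-voxel
#' random phase and amplitude; noise is temporally white Gaussian. The
#' volume is generated in subject space (planted centres are mapped through
#' the inverse of the subject-to-template affine).
#'
#' @param truth A `subject_truth`.
#' @param schedule A `block_schedule`.
#' @param space The acquisition grid (a `template_space`).
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @param TR_s Repetition time (default 3 s).
#' @param effect_fwhm_mm Effect blob FWHM (default 8 mm).
#' @param hrf HRF used for the planted response (default
#'   [double_gamma_hrf()]).
#' @return A `bold_volume`: list with `data` (n_volumes x n_voxels matrix),
#'   `space`, `TR_s`, `affine_subject_to_template`, `n_volumes`.
#' @export
generate_subject_bold <- function(truth, schedule, space, seed, TR_s = 3,
                                  effect_fwhm_mm = 8,
                                  hrf = double_gamma_hrf()) {
  stopifnot(inherits(truth, "subject_truth"), inherits(space, "template_space"))
  A <- truth$affine_subject_to_template
  if (abs(det(A)) < 1e-12) stop("non-invertible affine", call. = FALSE)
  A_inv <- solve(A)
  n_volumes <- as.integer(ceiling(schedule_duration(schedule) / TR_s))
  n_vox <- prod(space$grid_shape)
  t_s <- (seq_len(n_volumes) - 1) * TR_s

  # unit peak-to-peak condition responses
  unit_reg <- function(cond) {
    r <- make_regressor(schedule, cond, hrf, TR_s = TR_s, n_volumes = n_volumes)
    h <- attr(r, "height")
    if (h > 0) as.numeric(r) / h else as.numeric(r)
  }
  regs <- list(scenes = unit_reg("scenes"), objects = unit_reg("objects"))
  amps <- c(scenes = truth$amplitude_pct / 100,
            objects = truth$object_amplitude_pct / 100)

  to_subject_mm <- function(mm_t) as.numeric(A_inv %*% c(mm_t, 1))[1:3]

  Y <- with_seed(seed, {
    Y <- matrix(if (truth$noise_sd > 0)
      stats::rnorm(n_volumes * n_vox, 0, truth$noise_sd) else 0,
      nrow = n_volumes, ncol = n_vox)
    Y <- Y + truth$baseline
    if (truth$drift_amplitude > 0) {
      phase <- stats::runif(n_vox, 0, 2 * pi)
      amp <- truth$drift_amplitude * stats::runif(n_vox, 0.5, 1)
      w <- 2 * pi * t_s / 128
      Y <- Y + cos(w) %o% (amp * cos(phase)) - sin(w) %o% (amp * sin(phase))
    }
    for (cond in names(regs)) {
      if (amps[[cond]] <= 0) next
      for (roi_name in names(truth$center_mm)) {
        ctr_s <- to_subject_mm(truth$center_mm[[roi_name]])
        blob <- effect_blob(space, ctr_s, effect_fwhm_mm)
        if (!length(blob$idx)) next
        Y[, blob$idx] <- Y[, blob$idx] +
          truth$baseline * amps[[cond]] * (regs[[cond]] %o% blob$w)
      }
    }
    Y
  })
  structure(list(data = Y, space = space, TR_s = TR_s,
                 n_volumes = n_volumes,
                 affine_subject_to_template = A),
            class = "bold_volume")
}

# Draw one subject's truth record (deterministic in base_seed + i).
draw_subject_truth <- function(spec, i) {
  seed_i <- spec$base_seed + i
  with_seed(seed_i, {
    amp <- max(0, stats::rnorm(1, spec$amplitude_mean_pct, spec$amplitude_sd_pct))
    oamp <- max(0, stats::rnorm(1, spec$object_amplitude_mean_pct,
                                spec$object_amplitude_sd_pct))
    k <- floor(spec$max_shift_mm / spec$space$voxel_size)
    shift_mm <- if (k > 0) {
      sample(seq(-k, k), 3, replace = TRUE) * spec$space$voxel_size
    } else c(0, 0, 0)
    sub_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(spec$rois$masks) + 1L)
    A <- diag(4)
    A[1:3, 4] <- shift_mm   # template_mm = subject_mm + shift
    centers <- list()
    for (j in seq_along(spec$rois$masks)) {
      rn <- names(spec$rois$masks)[j]
      centers[[rn]] <- sample_subject_center(
        roi_consensus_centers()[[rn]], spec$jitter_sd_mm,
        spec$rois$masks[[rn]], spec$space, seed = sub_seeds[j])
    }
    list(truth = subject_truth(
      subject_id = i, center_mm = centers, amplitude_pct = amp,
      object_amplitude_pct = oamp, jitter_sd_mm = spec$jitter_sd_mm,
      noise_sd = spec$noise_sd, drift_amplitude = spec$drift_amplitude,
      baseline = spec$baseline, affine_subject_to_template = A),
      bold_seed = sub_seeds[length(sub_seeds)])
  })
}

#' Generate one subject of a cohort
#'
#' Streaming interface: generates the i-th subject (truth, BOLD volume and
#' subject-space ROI masks) of the cohort described by `spec`, so large
#' cohorts need not be held in memory at once. Deterministic given
#' `spec$base_seed + i`.
#'
#' @param spec A `cohort_spec`.
#' @param i Subject index (1-based).
#' @param schedule Block schedule (default [build_block_schedule()]).
#' @return List with `truth`, `bold`, `roi_masks` (subject space).
#' @export
generate_subject <- function(spec, i, schedule = build_block_schedule()) {
  stopifnot(inherits(spec, "cohort_spec"), i >= 1, i <= spec$n_subjects)
  drawn <- draw_subject_truth(spec, i)
  bold <- generate_subject_bold(drawn$truth, schedule, spec$space,
                                seed = drawn$bold_seed, TR_s = spec$TR_s,
                                effect_fwhm_mm = spec$effect_fwhm_mm)
  roi_masks <- lapply(names(spec$rois$masks), function(rn) {
    to_subject_space(spec$rois$masks[[rn]],
                     drawn$truth$affine_subject_to_template,
                     spec$space, roi_name = rn)
  })
  names(roi_masks) <- names(spec$rois$masks)
  list(truth = drawn$truth, bold = bold, roi_masks = roi_masks)
}

#' Draw the ground-truth records of a cohort without generating BOLD data
#'
#' Uses exactly the per-subject random streams of [generate_subject()], so
#' the truths match those of a full generation with the same spec.
#'
#' @param spec A `cohort_spec`.
#' @return List of `subject_truth` objects.
#' @export
cohort_truths <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(i) draw_subject_truth(spec, i)$truth)
}

#' Generate a full synthetic cohort
#'
#' Calls [generate_subject()] for every subject. Generation is a pure
#' function of the spec: regenerating with the same `base_seed` reproduces
#' identical truth records and volumes.
#'
#' @param spec A `cohort_spec`.
#' @param schedule Block schedule (default [build_block_schedule()]).
#' @param keep_bold Keep the BOLD matrices in the result (default TRUE);
#'   set FALSE to return truth and masks only.
#' @return A `cohort`: list with `spec`, `schedule`, `subjects` (list of
#'   per-subject lists as from [generate_subject()]).
#' @export
generate_cohort <- function(spec, schedule = build_block_schedule(),
                            keep_bold = TRUE) {
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    s <- generate_subject(spec, i, schedule)
    if (!keep_bold) s$bold <- NULL
    s
  })
  structure(list(spec = spec, schedule = schedule, subjects = subjects),
            class = "cohort")
}
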