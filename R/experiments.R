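# Calibration and recovery experiments on synthetic cohorts. These are the
# package's statistical self-checks: each runs a fully specified simulation
# and returns the measured quantity together with the conditions used.

#' GLM agreement with the brute-force normal equations
#'
#' Fits random small instances (<= 8 time points x 5 voxels) with
#' [fit_glm()] and with a direct `solve(X'X) X'y` evaluation, and reports
#' the largest absolute discrepancy in betas and residual variances.
#'
#' @param n_instances Number of random instances (default 100).
#' @param seed RNG seed.
#' @return List with `max_abs_diff`, `n_instances`.
#' @export
glm_oracle_check <- function(n_instances = 100, seed = 1) {
  worst <- 0
  with_seed(seed, {
    for (r in seq_len(n_instances)) {
      n <- sample(5:8, 1)
      p <- sample(2:min(4, n - 1), 1)
      X <- cbind(matrix(stats::rnorm(n * (p - 1)), n), 1)
      colnames(X) <- c(paste0("c", seq_len(p - 1)), "constant")
      Y <- matrix(stats::rnorm(n * 5), n, 5)
      fit <- fit_glm(Y, X)
      xtx_inv <- solve(t(X) %*% X)
      for (v in 1:5) {
        beta <- xtx_inv %*% t(X) %*% Y[, v]
        s2 <- sum((Y[, v] - X %*% beta)^2) / (n - p)
        worst <- max(worst,
                     max(abs(fit$betas[, v] - as.numeric(beta))),
                     abs(fit$sigma2[v] - s2))
      }
    }
  })
  list(max_abs_diff = worst, n_instances = n_instances)
}

#' Planted-null calibration of the individual-level Z maps
#'
#' Generates an amplitude-0 cohort (all condition effects zero, noise and
#' drift at their defaults), fits the unsmoothed scenes > objects Z maps
#' and measures the fraction of in-ROI voxels exceeding `z_threshold`,
#' together with the one-sided normal tail it should match and the
#' binomial standard error of the comparison.
#'
#' @param n_subjects Cohort size (default 10).
#' @param grid_shape Template grid (default 30 x 36 x 30).
#' @param base_seed Cohort seed.
#' @param z_threshold Tail threshold (default 3.9).
#' @return List: `fraction`, `expected`, `count`, `n_voxels`, `se`,
#'   `within_3se`.
#' @export
null_tail_calibration <- function(n_subjects = 10, grid_shape = c(30L, 36L, 30L),
                                  base_seed = 1, z_threshold = 3.9) {
  space <- template_space(grid_shape)
  rois <- make_template_rois(space)
  spec <- cohort_spec(n_subjects = n_subjects, base_seed = base_seed,
                      space = space, rois = rois,
                      amplitude_mean_pct = 0, amplitude_sd_pct = 0,
                      object_amplitude_mean_pct = 0,
                      object_amplitude_sd_pct = 0, jitter_sd_mm = 0)
  schedule <- build_block_schedule()
  design <- build_design_matrix(schedule, TR_s = spec$TR_s)
  count <- 0L; total <- 0L
  for (i in seq_len(n_subjects)) {
    s <- generate_subject(spec, i, schedule)
    m <- Reduce(`|`, s$roi_masks)
    Yf <- highpass(s$bold$data[, which(m), drop = FALSE], sigma_s = 50,
                   TR_s = spec$TR_s)
    fit <- fit_glm(Yf, design, mask = which(m))
    zm <- contrast_zmap(fit, "scenes>objects")
    zin <- zm$data   # matrix-input fit: values are the masked voxels
    count <- count + sum(zin > z_threshold)
    total <- total + length(zin)
  }
  expected <- stats::pnorm(z_threshold, lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / total)
  fraction <- count / total
  list(fraction = fraction, expected = expected, count = count,
       n_voxels = total, se = se,
       within_3se = abs(fraction - expected) <= 3 * se)
}

#' Family-wise error calibration of the permutation cluster correction
#'
#' Repeatedly applies [cluster_extent_correct()] to pure-noise cohorts of
#' per-subject Gaussian contrast maps and reports the fraction of
#' replicates in which any cluster is declared significant. Under the null
#' this should match the nominal `alpha`. The noise maps are smoothed with
#' the same 5 mm kernel at which the group stage operates: at that
#' smoothness null cluster extents are large enough that the integer-valued
#' maximum-extent statistic has essentially no tie mass at its upper
#' quantiles (on unsmoothed white noise the null maxima concentrate on a
#' handful of small integers, which makes the exact permutation test
#' noticeably conservative).
#'
#' @param n_replicates Number of null cohorts (default 200).
#' @param n_subjects Subjects per cohort (default 10).
#' @param grid_shape Template grid (default 30 x 36 x 30).
#' @param n_perm Permutations per test (default 199).
#' @param alpha Nominal FWE level (default 0.05).
#' @param z_form Cluster-forming threshold (default 2.3).
#' @param smooth_fwhm_mm Smoothness of the null maps (default 5 mm at 2 mm
#'   voxels; 0 for white noise).
#' @param seed RNG seed.
#' @return List: `fwe_rate`, `n_replicates`, `ci95` (binomial 95% CI around
#'   `alpha`), `within_ci`.
#' @export
fwe_null_calibration <- function(n_replicates = 200, n_subjects = 10,
                                 grid_shape = c(30L, 36L, 30L), n_perm = 199,
                                 alpha = 0.05, z_form = 2.3,
                                 smooth_fwhm_mm = 5, seed = 1) {
  n_vox <- prod(grid_shape)
  hits <- with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    vapply(seq_len(n_replicates), function(r) {
      maps <- lapply(seq_len(n_subjects), function(i)
        smooth_volume(array(stats::rnorm(n_vox), dim = grid_shape),
                      smooth_fwhm_mm, 2))
      res <- cluster_extent_correct(maps, z_form = z_form, alpha = alpha,
                                    n_perm = n_perm, seed = rep_seeds[r])
      any(res$significant)
    }, logical(1))
  })
  rate <- mean(hits)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_replicates)
  ci <- c(alpha - half, alpha + half)
  list(fwe_rate = rate, n_replicates = n_replicates, ci95 = ci,
       within_ci = rate >= ci[1] & rate <= ci[2])
}

#' Power of the permutation cluster correction for a planted effect
#'
#' Adds a cuboid effect of the given amplitude (in noise-SD units) to
#' every subject's standard-normal map and measures how often the planted
#' cluster survives correction.
#'
#' @param n_replicates Number of cohorts (default 20).
#' @param n_subjects Subjects per cohort (default 10).
#' @param grid_shape Template grid (default 20^3, the effect is central).
#' @param amplitude Effect height in noise-SD units (default 2).
#' @param seed RNG seed.
#' @return List: `power`, `n_replicates`.
#' @export
fwe_power_check <- function(n_replicates = 20, n_subjects = 10,
                            grid_shape = c(20L, 20L, 20L), amplitude = 2,
                            seed = 1) {
  lo <- round(grid_shape / 2) - 1L; hi <- lo + 3L
  blob <- array(0, dim = grid_shape)
  blob[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- amplitude
  centre <- round(grid_shape / 2)
  hits <- with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    vapply(seq_len(n_replicates), function(r) {
      maps <- lapply(seq_len(n_subjects), function(i)
        blob + array(stats::rnorm(prod(grid_shape)), dim = grid_shape))
      res <- cluster_extent_correct(maps, n_perm = 199, seed = rep_seeds[r])
      res$mask[centre[1], centre[2], centre[3]]
    }, logical(1))
  })
  list(power = mean(hits), n_replicates = n_replicates)
}

#' Overlap-peak recovery of the planted consensus location
#'
#' Generates cohorts with zero jitter and a fixed 3% scene amplitude as the
#' only planted effect (object amplitude 0; noise and drift at their
#' defaults), builds the unsmoothed overlap map and asks, per replicate,
#' whether the in-ROI overlap peak (raster tie-break) falls exactly on the
#' planted consensus voxel of the parahippocampal ROI at Z = 2.3, the
#' threshold at which overlap is conventionally reported. Also checks that
#' each ROI's activation count is non-increasing in the Z threshold in
#' every replicate. Note that exact-voxel recovery is a demanding measure:
#' with an 8 mm effect blob on a 2 mm grid, adjacent voxels have nearly the
#' centre's activation probability, so the argmax frequently lands one
#' voxel off even when the planted location is correct on average.
#'
#' @param n_replicates Number of cohorts (default 20).
#' @param n_subjects Subjects per cohort (default 20).
#' @param grid_shape Template grid (default 30 x 36 x 30).
#' @param seed RNG seed (per-replicate cohort seeds derive from it).
#' @param roi ROI evaluated for peak recovery (default `"PHG"`).
#' @param z_eval Threshold of the evaluated overlap map (default 2.3).
#' @return List: `recovery_pct`, `monotone_pct`, `n_replicates`,
#'   `successes`.
#' @export
overlap_recovery_experiment <- function(n_replicates = 20, n_subjects = 20,
                                        grid_shape = c(30L, 36L, 30L),
                                        seed = 1, roi = "PHG", z_eval = 2.3) {
  space <- template_space(grid_shape)
  rois <- make_template_rois(space)
  consensus_vox <- round(mm_to_vox(space, roi_consensus_centers()[[roi]]))
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - n_replicates - 1L,
                                    n_replicates))
  success <- logical(n_replicates)
  monotone <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(n_subjects = n_subjects, base_seed = rep_seeds[r],
                        space = space, rois = rois,
                        amplitude_mean_pct = 3, amplitude_sd_pct = 0,
                        object_amplitude_mean_pct = 0,
                        object_amplitude_sd_pct = 0, jitter_sd_mm = 0)
    res <- analyse_cohort(spec, fwhms = 0, keep_copes = FALSE,
                          group_fwhm = NA)
    om <- res$overlap[[as.character(z_eval)]]
    n_active <- sum(res$records$active[res$records$roi == roi &
                                         res$records$z_threshold == z_eval])
    if (n_active > 0) {
      pk <- overlap_peak(om, rois$masks[[roi]], n_active, space = space)
      success[r] <- all(pk$vox == consensus_vox)
    }
    monotone[r] <- all(vapply(unique(res$records$roi), function(rn) {
      counts <- vapply(c(2.3, 3.1, 3.9), function(thr)
        sum(res$records$active[res$records$roi == rn &
                                 res$records$z_threshold == thr]), numeric(1))
      all(diff(counts) <= 0)
    }, logical(1)))
  }
  list(recovery_pct = 100 * mean(success),
       monotone_pct = 100 * mean(monotone),
       n_replicates = n_replicates, successes = sum(success))
}
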