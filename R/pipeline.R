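# Orchestration: per-subject analysis drivers, cohort-level aggregation,
# config validation and the end-to-end pipeline runner used by the
# numbered scripts under analysis/.

#' First-level analysis of one synthetic subject
#'
#' For each smoothing level: smooth the BOLD volumes (data-level smoothing),
#' high-pass filter, fit the voxel-wise GLM and form the contrast Z map.
#' Then, per threshold and ROI, record whether the subject has
#' suprathreshold in-ROI voxels; binarise the unsmoothed map at each
#' threshold and resample it to template space; extract per-ROI peak
#' records (unsmoothed maps); and compute percent signal change per ROI and
#' condition. When every requested smoothing level is 0 the fit is
#' restricted to the union of the subject's ROI voxels (voxel-wise
#' statistics are unaffected by the restriction).
#'
#' @param subject A list as from [generate_subject()] (`bold`, `truth`,
#'   `roi_masks`).
#' @param design A `design_matrix` (already high-passed).
#' @param thresholds Z thresholds (default 2.3, 3.1, 3.9).
#' @param fwhms Smoothing FWHMs in mm (default 0, 2, 5).
#' @param contrast Contrast name (default `"scenes>objects"`).
#' @param hc_split_y_mm Hippocampal long-axis boundary (default -21).
#' @param group_fwhm Smoothing level of the contrast effect map passed to
#'   the group stage (default 5 if present in `fwhms`, else the first).
#' @return List: `records` (activation flags data.frame), `template_binary`
#'   (per-threshold unsmoothed template-space binary maps), `peaks`
#'   (data.frame over ROIs x thresholds), `psc` (data.frame), `cope_template`
#'   (template-space contrast effect map for the group stage).
#' @export
analyse_subject <- function(subject, design, thresholds = c(2.3, 3.1, 3.9),
                            fwhms = c(0, 2, 5), contrast = "scenes>objects",
                            hc_split_y_mm = -21, group_fwhm = NULL) {
  bold <- subject$bold
  space <- bold$space
  A <- bold$affine_subject_to_template
  if (is.null(group_fwhm)) {
    group_fwhm <- if (5 %in% fwhms) 5 else fwhms[1]
  }   # NA skips the group-stage effect map entirely
  roi_union <- Reduce(`|`, subject$roi_masks)
  restrict <- all(fwhms == 0)
  mask <- if (restrict) roi_union else NULL

  records <- list(); peaks <- list(); template_binary <- list()
  cope_template <- NULL
  unsmoothed_fit <- NULL

  for (fw in fwhms) {
    Y <- bold$data
    if (fw > 0) {
      for (v in seq_len(nrow(Y))) {
        Y[v, ] <- as.numeric(smooth_volume(array(Y[v, ], dim = space$grid_shape),
                                           fw, space$voxel_size))
      }
    }
    Yf <- if (is.null(mask)) Y else Y[, which(mask), drop = FALSE]
    Yf <- highpass(Yf, sigma_s = 50, TR_s = bold$TR_s)
    fake_bold <- structure(list(data = Yf, space = space, TR_s = bold$TR_s,
                                n_volumes = bold$n_volumes,
                                affine_subject_to_template = A),
                           class = "bold_volume")
    fit <- fit_glm(fake_bold, design,
                   mask = if (is.null(mask)) NULL else which(mask))
    zm <- contrast_zmap(fit, contrast, fwhm_mm = fw)
    if (fw == 0) unsmoothed_fit <- fit
    if (!is.na(group_fwhm) && fw == group_fwhm) {
      cs <- contrast_spec(contrast)
      w <- numeric(nrow(fit$betas)); names(w) <- rownames(fit$betas)
      w[names(cs$weights)] <- cs$weights
      cope <- array(0, dim = space$grid_shape)
      cope[fit$voxels] <- as.numeric(w %*% fit$betas)
      cope_template <- map_to_template(cope, A, space)
    }
    for (thr in thresholds) {
      spec <- threshold_spec(thr, fw)
      for (rn in names(subject$roi_masks)) {
        act <- roi_has_activation(zm, subject$roi_masks[[rn]], spec)
        records[[length(records) + 1L]] <- data.frame(
          subject = subject$truth$subject_id, roi = rn, z_threshold = thr,
          fwhm = fw, active = act$active, n_voxels = act$n_voxels,
          stringsAsFactors = FALSE)
      }
      if (fw == 0) {
        bin <- threshold_zmap(zm, spec)
        template_binary[[as.character(thr)]] <-
          map_to_template(bin$data, A, space)
        for (rn in names(subject$roi_masks)) {
          pk <- peak_in_roi(zm, subject$roi_masks[[rn]], z_threshold = thr,
                            subject_id = subject$truth$subject_id,
                            roi_name = rn,
                            hc_split_y_mm = if (rn == "HC") hc_split_y_mm)
          pk$z_threshold <- thr
          # report the peak in template space for cross-subject plots
          mm_t <- as.numeric(A %*% c(pk$x_mm, pk$y_mm, pk$z_mm, 1))[1:3]
          pk$x_mm <- mm_t[1]; pk$y_mm <- mm_t[2]; pk$z_mm <- mm_t[3]
          pk$hemisphere <- if (mm_t[1] >= 0) "R" else "L"
          if (rn == "HC") {
            pk$long_axis <- if (mm_t[2] >= hc_split_y_mm) "anterior" else "posterior"
          }
          peaks[[length(peaks) + 1L]] <- pk
        }
      }
    }
  }

  psc <- list()
  if (!is.null(unsmoothed_fit)) {
    for (rn in names(subject$roi_masks)) {
      for (cond in c("scenes", "objects")) {
        psc[[length(psc) + 1L]] <- data.frame(
          subject = subject$truth$subject_id, roi = rn, condition = cond,
          psc = percent_signal_change(unsmoothed_fit, cond,
                                      subject$roi_masks[[rn]]),
          stringsAsFactors = FALSE)
      }
    }
  }

  list(records = do.call(rbind, records),
       template_binary = template_binary,
       peaks = do.call(rbind, peaks),
       psc = do.call(rbind, psc),
       cope_template = cope_template)
}

#' Cohort-level localiser analysis
#'
#' Streams subjects through [generate_subject()] and [analyse_subject()],
#' accumulating activation records, peak records, percent signal change,
#' per-threshold overlap maps (from the unsmoothed binarised template-space
#' maps) and the per-subject contrast effect maps for the group stage.
#'
#' @param spec A `cohort_spec`.
#' @param thresholds,fwhms,contrast,hc_split_y_mm,group_fwhm Passed to
#'   [analyse_subject()].
#' @param keep_copes Keep per-subject template contrast maps (default TRUE).
#' @param progress Print one line per subject (default FALSE).
#' @return List: `records`, `peaks`, `psc`, `overlap` (list of
#'   `overlap_map` per threshold), `copes` (list of arrays), `spec`,
#'   `design`, `truths`.
#' @export
analyse_cohort <- function(spec, thresholds = c(2.3, 3.1, 3.9),
                           fwhms = c(0, 2, 5), contrast = "scenes>objects",
                           hc_split_y_mm = spec$rois$hc_split_y_mm,
                           group_fwhm = NULL, keep_copes = TRUE,
                           progress = FALSE) {
  schedule <- build_block_schedule()
  design <- build_design_matrix(schedule, TR_s = spec$TR_s)
  records <- list(); peaks <- list(); psc <- list(); truths <- list()
  copes <- list()
  acc <- lapply(thresholds, function(...) NULL)
  names(acc) <- as.character(thresholds)
  for (i in seq_len(spec$n_subjects)) {
    subj <- generate_subject(spec, i, schedule)
    res <- analyse_subject(subj, design, thresholds = thresholds,
                           fwhms = fwhms, contrast = contrast,
                           hc_split_y_mm = hc_split_y_mm,
                           group_fwhm = group_fwhm)
    records[[i]] <- res$records
    peaks[[i]] <- res$peaks
    psc[[i]] <- res$psc
    truths[[i]] <- subj$truth
    if (keep_copes) copes[[i]] <- res$cope_template
    for (thr in names(res$template_binary)) {
      b <- as.integer(res$template_binary[[thr]])
      acc[[thr]] <- if (is.null(acc[[thr]])) b else acc[[thr]] + b
    }
    if (progress) message(sprintf("subject %d/%d done", i, spec$n_subjects))
  }
  overlap <- lapply(names(acc), function(thr) {
    structure(list(data = array(acc[[thr]], dim = spec$space$grid_shape),
                   n_total = spec$n_subjects, n_maps = spec$n_subjects),
              class = "overlap_map")
  })
  names(overlap) <- names(acc)
  list(records = do.call(rbind, records), peaks = do.call(rbind, peaks),
       psc = do.call(rbind, psc), overlap = overlap, copes = copes,
       spec = spec, design = design, truths = truths)
}

#' Consistency table across ROIs and thresholds
#'
#' One row per ROI x threshold: number of subjects with significant in-ROI
#' activation, the overlap peak (count, percent of active subjects,
#' coordinate), its distance to the group peak for that ROI, and the
#' anterior fraction of individual HC peaks.
#'
#' @param cohort_res Result of [analyse_cohort()].
#' @param group_peaks Optional named list of per-ROI group peak coordinates
#'   (mm); default the in-ROI peak of the group one-sample Z map built from
#'   the cohort's contrast maps.
#' @param fwhm Smoothing level of the activation counts (default 0, the
#'   level the overlap maps are built from).
#' @return A data.frame (`consistency_table`).
#' @export
consistency_table <- function(cohort_res, group_peaks = NULL, fwhm = 0) {
  spec <- cohort_res$spec
  space <- spec$space
  rois <- spec$rois$masks
  if (is.null(group_peaks)) {
    gz <- group_one_sample_z(cohort_res$copes, space = space)
    group_peaks <- lapply(rois, function(m) {
      idx <- which(m)
      best <- idx[which.max(gz$data[idx])]
      vox_to_mm(space, as.numeric(arrayInd(best, dim(gz$data))))
    })
  }
  rows <- list()
  for (thr in names(cohort_res$overlap)) {
    om <- cohort_res$overlap[[thr]]
    for (rn in names(rois)) {
      sel <- cohort_res$records$roi == rn &
        cohort_res$records$z_threshold == as.numeric(thr) &
        cohort_res$records$fwhm == fwhm
      n_active <- sum(cohort_res$records$active[sel])
      if (n_active == 0) next
      pk <- overlap_peak(om, rois[[rn]], n_active, space = space)
      hc_sel <- cohort_res$peaks$roi == "HC" &
        cohort_res$peaks$z_threshold == as.numeric(thr) &
        cohort_res$peaks$suprathreshold
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rn, z_threshold = as.numeric(thr), fwhm = fwhm,
        n_active = n_active, peak_count = pk$count,
        pct_of_active = pk$pct_of_active,
        peak_x_mm = pk$mm[1], peak_y_mm = pk$mm[2], peak_z_mm = pk$mm[3],
        dist_to_group_peak_mm = peak_distance(pk$mm, group_peaks[[rn]]),
        anterior_fraction_pct = if (rn == "HC" && any(hc_sel))
          anterior_fraction(cohort_res$peaks[hc_sel, , drop = FALSE],
                            spec$rois$hc_split_y_mm) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("consistency_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Config validation and end-to-end runner

.config_defaults <- function() {
  list(n_subjects = 6L, base_seed = 1L,
       grid_shape = c(40L, 48L, 40L), voxel_size = 2,
       thresholds = c(2.3, 3.1, 3.9), fwhms = c(0, 2, 5),
       contrast = "scenes>objects", y_split_mm = -21,
       amplitude_mean_pct = 3, amplitude_sd_pct = 1,
       object_amplitude_mean_pct = 1.5, object_amplitude_sd_pct = 0.5,
       jitter_sd_mm = 4, noise_sd = 50, drift_amplitude = 10,
       baseline = 1000, max_shift_mm = 4,
       n_perm = 199L, alpha = 0.05, z_form = 2.3,
       out_dir = "out", write_volumes = FALSE)
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a JSON file; unknown keys are
#' rejected (listing every offending field), defaults are filled, and
#' units/signs are checked (thresholds > 0, fwhm >= 0, non-empty lists).
#'
#' @param raw Named list or JSON file path.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  stopifnot(is.list(raw))
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  problems <- character(0)
  if (length(cfg$thresholds) == 0) problems <- c(problems, "thresholds: empty")
  if (any(cfg$thresholds <= 0)) problems <- c(problems, "thresholds: must be > 0")
  if (length(cfg$fwhms) == 0) problems <- c(problems, "fwhms: empty")
  if (any(cfg$fwhms < 0)) problems <- c(problems, "fwhms: must be >= 0")
  if (cfg$n_subjects < 1) problems <- c(problems, "n_subjects: must be >= 1")
  if (cfg$n_perm < 100) problems <- c(problems, "n_perm: must be >= 100")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) problems <- c(problems, "alpha: in (0,1)")
  if (any(c(cfg$amplitude_sd_pct, cfg$object_amplitude_sd_pct,
            cfg$jitter_sd_mm, cfg$noise_sd, cfg$drift_amplitude) < 0)) {
    problems <- c(problems, "distribution SDs/amplitudes: must be >= 0")
  }
  if (length(problems)) {
    stop("invalid config: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline: simulate, fit, localise, overlap, group, report
#'
#' Executes every stage on the synthetic cohort described by the config and
#' writes publication-style tables (activation frequencies, overlap
#' consistency, group peaks) plus overlap/group volumes under
#' `cfg$out_dir`. Re-running with an unchanged config reproduces
#' byte-identical tables.
#'
#' @param cfg A `pipeline_config` (see [validate_config()]), or a raw list
#'   / JSON path that will be validated first.
#' @return A `run_report`: per-stage status, output manifest with MD5
#'   checksums, and the three tables.
#' @export
run_pipeline <- function(cfg = validate_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  t0 <- Sys.time()
  dirs <- file.path(cfg$out_dir, c("subjects", "maps", "overlap", "group",
                                   "tables"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  stage_status <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stage_status[[name]] <<- sprintf("ok (%.1f s)",
                                     as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  space <- template_space(cfg$grid_shape, cfg$voxel_size)
  rois <- make_template_rois(space, hc_split_y_mm = cfg$y_split_mm)
  spec <- cohort_spec(
    n_subjects = cfg$n_subjects, base_seed = cfg$base_seed, space = space,
    rois = rois, amplitude_mean_pct = cfg$amplitude_mean_pct,
    amplitude_sd_pct = cfg$amplitude_sd_pct,
    object_amplitude_mean_pct = cfg$object_amplitude_mean_pct,
    object_amplitude_sd_pct = cfg$object_amplitude_sd_pct,
    jitter_sd_mm = cfg$jitter_sd_mm, noise_sd = cfg$noise_sd,
    drift_amplitude = cfg$drift_amplitude, baseline = cfg$baseline,
    max_shift_mm = cfg$max_shift_mm)

  res <- run_stage("simulate+fit+localise", function() {
    analyse_cohort(spec, thresholds = cfg$thresholds, fwhms = cfg$fwhms,
                   contrast = cfg$contrast, hc_split_y_mm = cfg$y_split_mm)
  })

  freq <- run_stage("frequency", function() frequency_table(res$records))
  cons <- run_stage("overlap", function() consistency_table(res))

  group <- run_stage("group", function() {
    gz <- group_one_sample_z(res$copes, space = space)
    corr <- cluster_extent_correct(res$copes, z_form = cfg$z_form,
                                   alpha = cfg$alpha, n_perm = cfg$n_perm,
                                   seed = cfg$base_seed)
    peaks <- lapply(names(rois$masks), function(rn) {
      idx <- which(rois$masks[[rn]])
      best <- idx[which.max(gz$data[idx])]
      mm <- vox_to_mm(space, as.numeric(arrayInd(best, dim(gz$data))))
      data.frame(roi = rn, x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
                 peak_z = gz$data[best],
                 in_significant_cluster = corr$mask[best],
                 stringsAsFactors = FALSE)
    })
    list(gz = gz, corr = corr, peaks = do.call(rbind, peaks))
  })

  # outputs
  files <- character(0)
  add <- function(p) { files <<- c(files, p); p }
  write_schedule_tsv(build_block_schedule(),
                     add(file.path(cfg$out_dir, "subjects", "schedule.tsv")))
  for (i in seq_along(res$truths)) {
    write_truth_json(res$truths[[i]],
                     add(file.path(cfg$out_dir, "subjects",
                                   sprintf("truth_%02d.json", i))))
    write_affine(res$truths[[i]]$affine_subject_to_template,
                 add(file.path(cfg$out_dir, "subjects",
                               sprintf("affine_%02d.txt", i))))
  }
  if (cfg$write_volumes) {
    for (i in seq_along(res$copes)) {
      write_volume_nifti(res$copes[[i]], space,
                         add(file.path(cfg$out_dir, "maps",
                                       sprintf("cope_%02d.nii.gz", i))))
    }
  }
  for (thr in names(res$overlap)) {
    write_volume_nifti(res$overlap[[thr]]$data, space,
                       add(file.path(cfg$out_dir, "overlap",
                                     sprintf("overlap_z%s.nii.gz", thr))))
  }
  write_volume_nifti(group$gz$data, space,
                     add(file.path(cfg$out_dir, "group", "group_z.nii.gz")))
  write_volume_nifti(group$corr$mask * 1, space,
                     add(file.path(cfg$out_dir, "group",
                                   "group_significant_mask.nii.gz")))
  jsonlite::write_json(
    list(z_form = cfg$z_form, alpha = cfg$alpha, n_perm = cfg$n_perm,
         seed = cfg$base_seed, base_seed = cfg$base_seed,
         n_subjects = cfg$n_subjects),
    add(file.path(cfg$out_dir, "group", "permutation_settings.json")),
    auto_unbox = TRUE, digits = NA)
  write_tsv(freq, add(file.path(cfg$out_dir, "tables", "frequency.tsv")))
  write_tsv(cons, add(file.path(cfg$out_dir, "tables", "consistency.tsv")))
  write_tsv(res$peaks, add(file.path(cfg$out_dir, "tables", "peaks.tsv")))
  write_tsv(res$psc, add(file.path(cfg$out_dir, "tables", "psc.tsv")))
  write_tsv(group$peaks, add(file.path(cfg$out_dir, "tables",
                                       "group_peaks.tsv")))

  manifest <- data.frame(path = files, md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  structure(list(config = cfg, stages = stage_status, manifest = manifest,
                 frequency = freq, consistency = cons,
                 group_peaks = group$peaks,
                 elapsed_s = as.numeric(Sys.time() - t0, units = "secs")),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d output files, %.1f s\n",
              nrow(x$manifest), x$elapsed_s))
  for (s in names(x$stages)) cat(sprintf("  %-24s %s\n", s, x$stages[[s]]))
  invisible(x)
}
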