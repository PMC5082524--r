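#!/usr/bin/env Rscript
# Stage 4 -- probabilistic overlap consistency.
#
# Loads the per-threshold overlap maps (voxel-wise subject counts built
# from the unsmoothed binarised maps), finds each ROI's overlap peak, its
# percentage of activating subjects, its distance to the group-level peak,
# and the anterior fraction of individual hippocampal peaks.

source("analysis/00_config.R")

records <- read_tsv(file.path(RESULTS, "first_level",
                              "activation_records.tsv"))
peaks <- read_tsv(file.path(RESULTS, "first_level", "peaks.tsv"))
copes <- lapply(seq_len(N_SUBJECTS), function(i)
  read_volume_nifti(file.path(RESULTS, "first_level",
                              sprintf("cope_%02d.nii.gz", i)))$data)

gz <- group_one_sample_z(copes, space = SPACE)
group_peaks <- lapply(ROIS$masks, function(m) {
  idx <- which(m)
  best <- idx[which.max(gz$data[idx])]
  vox_to_mm(SPACE, as.numeric(arrayInd(best, dim(gz$data))))
})

rows <- list()
for (thr in THRESHOLDS) {
  om_arr <- read_volume_nifti(file.path(RESULTS, "overlap",
                                        sprintf("overlap_z%g.nii.gz",
                                                thr)))$data
  om <- structure(list(data = array(as.integer(om_arr), dim = GRID),
                       n_total = N_SUBJECTS, n_maps = N_SUBJECTS),
                  class = "overlap_map")
  for (rn in names(ROIS$masks)) {
    n_active <- sum(records$active[records$roi == rn &
                                     records$z_threshold == thr &
                                     records$fwhm == 0])
    if (n_active == 0) next
    pk <- overlap_peak(om, ROIS$masks[[rn]], n_active, space = SPACE)
    hc_sel <- peaks$roi == "HC" & peaks$z_threshold == thr &
      peaks$suprathreshold
    rows[[length(rows) + 1]] <- data.frame(
      roi = rn, z_threshold = thr, n_active = n_active,
      peak_count = pk$count, pct_of_active = pk$pct_of_active,
      x_mm = pk$mm[1], y_mm = pk$mm[2], z_mm = pk$mm[3],
      dist_to_group_peak_mm = peak_distance(pk$mm, group_peaks[[rn]]),
      anterior_fraction_pct = if (rn == "HC" && any(hc_sel))
        anterior_fraction(peaks[hc_sel, ], ROIS$hc_split_y_mm)
      else NA_integer_)
  }
}
cons <- do.call(rbind, rows)
write_tsv(cons, res_path("tables", "consistency.tsv"))

cat("overlap consistency (unsmoothed maps):\n")
for (i in seq_len(nrow(cons))) {
  cat(sprintf(paste0("  %-4s Z=%.1f  peak %2d/%2d active (%3d%%) at ",
                     "(%g, %g, %g), %4.1f mm from group peak%s\n"),
              cons$roi[i], cons$z_threshold[i], cons$peak_count[i],
              cons$n_active[i], cons$pct_of_active[i], cons$x_mm[i],
              cons$y_mm[i], cons$z_mm[i], cons$dist_to_group_peak_mm[i],
              ifelse(is.na(cons$anterior_fraction_pct[i]), "",
                     sprintf("; %d%% of HC peaks anterior",
                             cons$anterior_fraction_pct[i]))))
}
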