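#!/usr/bin/env Rscript
# Stage 1 -- simulate the localiser cohort.
#
# Draws the ground truth for every subject (planted effect centres,
# amplitudes, head offsets) and writes the block schedule, truth records
# and affines. BOLD volumes themselves are regenerated deterministically
# by later stages, so only one example volume is written here for
# inspection.

source("analysis/00_config.R")

sched <- build_block_schedule()
write_schedule_tsv(sched, res_path("cohort", "schedule.tsv"))
cat(sprintf("schedule: %d blocks (%d experimental), %g s total\n",
            nrow(sched), sum(sched$condition != "fixation"),
            schedule_duration(sched)))

truths <- cohort_truths(SPEC)
for (tr in truths) {
  write_truth_json(tr, res_path("cohort", sprintf("truth_%02d.json",
                                                  tr$subject_id)))
  write_affine(tr$affine_subject_to_template,
               res_path("cohort", sprintf("affine_%02d.txt", tr$subject_id)))
}
amp <- vapply(truths, function(t) t$amplitude_pct, numeric(1))
cat(sprintf("cohort: %d subjects, scene amplitude %.2f +/- %.2f %%\n",
            length(truths), mean(amp), sd(amp)))

s1 <- generate_subject(SPEC, 1, sched)
arr <- array(t(s1$bold$data), dim = c(GRID, s1$bold$n_volumes))
write_volume_nifti(arr[, , , 1:5], SPACE,
                   res_path("cohort", "subject01_bold_first5vols.nii.gz"))
for (rn in names(s1$roi_masks)) {
  write_volume_nifti(s1$roi_masks[[rn]] * 1, SPACE,
                     res_path("cohort", sprintf("subject01_mask_%s.nii.gz", rn)))
}
cat("wrote schedule, truth records, affines and an example volume under",
    file.path(RESULTS, "cohort"), "\n")
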