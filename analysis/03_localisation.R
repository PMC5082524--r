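#!/usr/bin/env Rscript
# Stage 3 -- individual-level localisation frequencies.
#
# Summarises the stage-2 activation records into the proportion of
# subjects with at least one suprathreshold scenes > objects voxel in each
# ROI, for every threshold x smoothing cell.

source("analysis/00_config.R")

records <- read_tsv(file.path(RESULTS, "first_level",
                              "activation_records.tsv"))
freq <- frequency_table(records, rois = names(ROIS$masks),
                        thresholds = THRESHOLDS, fwhms = FWHMS)
write_tsv(freq, res_path("tables", "frequency.tsv"))

cat("proportion of subjects with significant in-ROI clusters\n")
cat("(rows: ROI x threshold; columns: smoothing FWHM mm)\n\n")
for (rn in names(ROIS$masks)) {
  for (thr in THRESHOLDS) {
    p <- vapply(FWHMS, function(fw)
      freq$proportion[freq$roi == rn & freq$z_threshold == thr &
                        freq$fwhm == fw], numeric(1))
    cat(sprintf("  %-4s Z=%.1f   %s\n", rn, thr,
                paste(sprintf("%4.2f", p), collapse = "  ")))
  }
}
# sanity: frequencies can only drop as the threshold rises
stopifnot(all(vapply(names(ROIS$masks), function(rn) {
  all(vapply(FWHMS, function(fw) {
    p <- freq$proportion[freq$roi == rn & freq$fwhm == fw]
    all(diff(p[order(freq$z_threshold[freq$roi == rn & freq$fwhm == fw])]) <= 0)
  }, logical(1)))
}, logical(1))))
cat("\nfrequencies are non-increasing in the Z threshold for every ROI\n")
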