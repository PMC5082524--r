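# Shared configuration for the numbered analysis scripts.
#
# A desk-scale cohort: 12 subjects on a 30 x 36 x 30 grid at 2 mm, with the
# generator's default effect/noise structure (3 +/- 1 % scene amplitude,
# 1.5 +/- 0.5 % object amplitude, 4 mm centre jitter, 5 % noise, mild
# drift, whole-voxel head offsets). Everything downstream is deterministic
# given BASE_SEED.

library(sceneloc)

BASE_SEED <- 20160
N_SUBJECTS <- 12L
GRID <- c(30L, 36L, 30L)
THRESHOLDS <- c(2.3, 3.1, 3.9)
FWHMS <- c(0, 2, 5)
CONTRAST <- "scenes>objects"

SPACE <- template_space(GRID)
ROIS <- make_template_rois(SPACE)
SPEC <- cohort_spec(n_subjects = N_SUBJECTS, base_seed = BASE_SEED,
                    space = SPACE, rois = ROIS)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)
res_path <- function(...) {
  p <- file.path(RESULTS, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}
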