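# File interfaces: NIfTI-1 volumes, TSV tables, 4x4 affine text files,
# JSON truth records.

#' Write a 3-D/4-D volume as NIfTI-1
#'
#' The voxel-to-world affine of `space` is written into the sform/qform
#' (RAS convention, NIfTI 0-based voxel indices).
#'
#' @param vol 3-D or 4-D numeric/logical array (time last for 4-D).
#' @param space A `template_space`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(vol, space, path) {
  stopifnot(inherits(space, "template_space"))
  storage.mode(vol) <- "double"
  # NIfTI voxel indices are 0-based: world = origin + i0 * voxel_size
  aff <- diag(4)
  diag(aff)[1:3] <- space$voxel_size
  aff[1:3, 4] <- space$origin_mm
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume_nifti()]
#'
#' @param path NIfTI file path.
#' @return List with `data` (array), `space` (a `template_space`
#'   reconstructed from the stored affine).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- aff[1, 1]
  d <- dim(img)[1:3]
  space <- template_space(grid_shape = d, voxel_size = vs,
                          origin_mm = aff[1:3, 4])
  list(data = as.array(img), space = space)
}

#' Write a data.frame as TSV
#' @param df A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a block schedule as a 3-column events TSV
#'
#' Columns: onset_s, duration_s, condition.
#'
#' @param schedule A `block_schedule`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  write_tsv(schedule[, c("onset_s", "duration_s", "condition")], path)
}

#' Read an events TSV into a block schedule
#' @param path File path.
#' @return A `block_schedule` data.frame (positions in onset order).
#' @export
read_schedule_tsv <- function(path) {
  df <- read_tsv(path)
  df <- df[order(df$onset_s), , drop = FALSE]
  sched <- data.frame(position = seq_len(nrow(df)), condition = df$condition,
                      onset_s = df$onset_s, duration_s = df$duration_s,
                      stringsAsFactors = FALSE)
  class(sched) <- c("block_schedule", "data.frame")
  sched
}

#' Write a 4x4 affine as a 4-line whitespace-delimited text file (row-major)
#' @param affine 4x4 matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_affine <- function(affine, path) {
  stopifnot(all(dim(affine) == c(4, 4)))
  writeLines(apply(affine, 1, function(r) paste(format(r, digits = 17),
                                                collapse = " ")), path)
  invisible(path)
}

#' Read a 4x4 affine text file
#' @param path File path.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(all(dim(m) == c(4, 4)))
  dimnames(m) <- NULL
  m
}

#' Serialise a subject truth record to JSON
#' @param truth A `subject_truth`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$affine_subject_to_template <-
    as.numeric(t(x$affine_subject_to_template))  # row-major
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subject truth record from JSON
#' @param path File path.
#' @return A `subject_truth`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(x$affine_subject_to_template, 4, 4, byrow = TRUE)
  subject_truth(subject_id = x$subject_id,
                center_mm = lapply(x$center_mm, as.numeric),
                amplitude_pct = x$amplitude_pct,
                object_amplitude_pct = x$object_amplitude_pct,
                jitter_sd_mm = x$jitter_sd_mm, noise_sd = x$noise_sd,
                drift_amplitude = x$drift_amplitude, baseline = x$baseline,
                affine_subject_to_template = A)
}
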