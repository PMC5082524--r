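#' Build the localiser block schedule
#'
#' The localiser run comprises 40 contiguous 16-s blocks: fixation at block
#' positions 1, 14, 27 and 40, and 36 stimulus blocks arranged as three
#' category orders, each presented four times:
#' (1) objects, scenes, scrambled; (2) scrambled, scenes, objects;
#' (3) scenes, objects, scrambled. The orders cycle 1,2,3,1,2,3,... so each
#' category appears in 12 blocks and the run lasts 640 s.
#'
#' @param block_duration_s Block length in seconds (default 16).
#' @param orders List of character vectors giving the within-triplet
#'   category orders; the default is the three-order convention above.
#' @return A `block_schedule`: data.frame with columns `position`,
#'   `condition`, `onset_s`, `duration_s`.
#' @export
build_block_schedule <- function(block_duration_s = 16,
                                 orders = list(
                                   c("objects", "scenes", "scrambled"),
                                   c("scrambled", "scenes", "objects"),
                                   c("scenes", "objects", "scrambled"))) {
  stop_if_not_scalar_number(block_duration_s, "block_duration_s")
  stopifnot(block_duration_s > 0, length(orders) >= 1)
  n_repeats <- 4L
  triplets <- rep(seq_along(orders), n_repeats)
  stim <- unlist(orders[triplets], use.names = FALSE)
  fixation_positions <- c(1L, 14L, 27L, 40L)
  n_blocks <- length(stim) + length(fixation_positions)
  condition <- character(n_blocks)
  condition[fixation_positions] <- "fixation"
  condition[-fixation_positions] <- stim
  sched <- data.frame(
    position = seq_len(n_blocks),
    condition = condition,
    onset_s = (seq_len(n_blocks) - 1) * block_duration_s,
    duration_s = block_duration_s,
    stringsAsFactors = FALSE
  )
  class(sched) <- c("block_schedule", "data.frame")
  sched
}

#' Number of trials fitting in one block
#'
#' Each trial is a stimulus presentation followed by an inter-stimulus
#' interval; with the default 200 ms presentation and 800 ms ISI a 16-s
#' block holds 16 trials.
#'
#' @param block_duration_s Block length in seconds (default 16).
#' @param stim_ms Stimulus presentation time in ms (default 200).
#' @param isi_ms Inter-stimulus interval in ms (default 800).
#' @return Integer trial count.
#' @export
trials_per_block <- function(block_duration_s = 16, stim_ms = 200,
                             isi_ms = 800) {
  stopifnot(block_duration_s > 0, stim_ms > 0, isi_ms >= 0)
  as.integer(floor(block_duration_s * 1000 / (stim_ms + isi_ms)))
}

#' Total duration of a block schedule in seconds
#' @param schedule A `block_schedule`.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  max(schedule$onset_s + schedule$duration_s)
}

#' Sampled double-gamma haemodynamic response function
#'
#' Difference of two gamma densities, each parameterised by its mean lag and
#' standard deviation: a positive response peaking near `peak_delay_s` minus
#' `undershoot_ratio` times an undershoot response centred at
#' `undershoot_delay_s`. The curve is normalised to unit peak.
#'
#' @param dt_s Sampling step in seconds (default 0.1).
#' @param length_s Duration of the sampled kernel in seconds (>= 32).
#' @param peak_delay_s Mean lag of the positive gamma (default 6 s).
#' @param undershoot_delay_s Mean lag of the undershoot gamma (default 16 s).
#' @param dispersion_s Standard deviation of both gammas (default 3 s).
#' @param undershoot_ratio Undershoot amplitude relative to the response
#'   (default 1/6).
#' @return An `hrf` object: list with `dt_s`, `t_s`, `samples` and the
#'   parameter set.
#' @export
double_gamma_hrf <- function(dt_s = 0.1, length_s = 32,
                             peak_delay_s = 6, undershoot_delay_s = 16,
                             dispersion_s = 3, undershoot_ratio = 1 / 6) {
  stop_if_not_scalar_number(dt_s, "dt_s")
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  if (length_s < 32) stop("length_s must be >= 32 s", call. = FALSE)
  t_s <- seq(0, length_s, by = dt_s)
  gam <- function(mean_lag, sd) {
    shape <- (mean_lag / sd)^2
    rate <- mean_lag / sd^2
    stats::dgamma(t_s, shape = shape, rate = rate)
  }
  h <- gam(peak_delay_s, dispersion_s) -
    undershoot_ratio * gam(undershoot_delay_s, dispersion_s)
  h <- h / max(h)
  structure(list(dt_s = dt_s, t_s = t_s, samples = h,
                 peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 dispersion_s = dispersion_s,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf")
}

#' Condition regressor: HRF-convolved boxcar sampled at volume times
#'
#' Builds a unit boxcar over the condition's blocks at the HRF micro-time
#' resolution, convolves with the HRF, and samples the result at volume
#' acquisition times t = (k - 1) * TR, k = 1..n_volumes. Also records the
#' regressor's peak-to-peak height, used for percent-signal-change scaling.
#'
#' @param schedule A `block_schedule`.
#' @param condition Condition label present in the schedule.
#' @param hrf An `hrf` object.
#' @param TR_s Repetition time in seconds (default 3).
#' @param n_volumes Number of volumes.
#' @return Numeric regressor of length `n_volumes` with attribute `height`
#'   (peak-to-peak amplitude; 0 for an all-zero regressor).
#' @export
make_regressor <- function(schedule, condition, hrf, TR_s = 3, n_volumes) {
  known <- union(c("scenes", "objects", "scrambled", "fixation"),
                 unique(schedule$condition))
  if (!condition %in% known) {
    stop(sprintf("unknown condition label '%s'", condition), call. = FALSE)
  }
  stopifnot(inherits(hrf, "hrf"))
  dt <- hrf$dt_s
  total_s <- schedule_duration(schedule) + max(hrf$t_s)
  n_fine <- ceiling(total_s / dt) + 1L
  box <- numeric(n_fine)
  rows <- schedule[schedule$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    i0 <- floor(rows$onset_s[i] / dt) + 1L
    i1 <- min(n_fine, ceiling((rows$onset_s[i] + rows$duration_s[i]) / dt))
    box[i0:i1] <- 1
  }
  conv <- stats::convolve(box, rev(hrf$samples), type = "open")[seq_len(n_fine)] * dt
  # the FFT-based convolution leaves ~1e-16 noise where the true value is 0
  if (any(conv != 0)) conv[abs(conv) < 1e-9 * max(abs(conv))] <- 0
  vol_t <- (seq_len(n_volumes) - 1) * TR_s
  idx <- pmin(n_fine, round(vol_t / dt) + 1L)
  reg <- conv[idx]
  attr(reg, "height") <- diff(range(reg))
  reg
}

#' Assemble the GLM design matrix
#'
#' One HRF-convolved regressor per stimulus condition plus a constant
#' column; fixation is the implicit baseline. Columns are high-passed with
#' [highpass()] when `apply_highpass = TRUE` (the constant column is
#' unaffected because the filter restores the grand mean).
#'
#' @param schedule A `block_schedule`.
#' @param hrf An `hrf` (default [double_gamma_hrf()]).
#' @param TR_s Repetition time in seconds (default 3).
#' @param n_volumes Number of volumes; default `ceiling(duration / TR)`.
#' @param conditions Modelled conditions (default scenes, objects,
#'   scrambled).
#' @param apply_highpass Apply the sigma = 50 s high-pass to the condition
#'   columns (default TRUE).
#' @param hp_sigma_s High-pass sigma in seconds.
#' @return A `design_matrix`: list with `X` (n_volumes x (k+1) matrix,
#'   labelled columns, constant last), `TR_s`, `heights` (named peak-to-peak
#'   regressor heights), `conditions`.
#' @export
build_design_matrix <- function(schedule, hrf = double_gamma_hrf(), TR_s = 3,
                                n_volumes = NULL,
                                conditions = c("scenes", "objects", "scrambled"),
                                apply_highpass = TRUE, hp_sigma_s = 50) {
  if (is.null(n_volumes)) {
    n_volumes <- as.integer(ceiling(schedule_duration(schedule) / TR_s))
  }
  cols <- lapply(conditions, function(cc) {
    make_regressor(schedule, cc, hrf, TR_s = TR_s, n_volumes = n_volumes)
  })
  heights <- vapply(cols, attr, numeric(1), "height")
  names(heights) <- conditions
  X <- cbind(do.call(cbind, lapply(cols, as.numeric)), 1)
  colnames(X) <- c(conditions, "constant")
  if (apply_highpass) {
    for (j in seq_along(conditions)) {
      X[, j] <- highpass(X[, j], sigma_s = hp_sigma_s, TR_s = TR_s)
    }
  }
  structure(list(X = X, TR_s = TR_s, n_volumes = n_volumes,
                 heights = heights, conditions = conditions,
                 hp_sigma_s = if (apply_highpass) hp_sigma_s else NA_real_),
            class = "design_matrix")
}

#' Gaussian-weighted running-line high-pass filter
#'
#' At each time point a straight line is fitted to the series by least
#' squares with Gaussian weights (SD `sigma_s`) centred on that point; the
#' fitted value is subtracted and the series grand mean added back, so slow
#' trends are removed while the baseline level is preserved.
#'
#' @param series Numeric series (length >= 3), or a matrix with series in
#'   columns.
#' @param sigma_s Gaussian weighting SD in seconds (default 50).
#' @param TR_s Sampling interval in seconds.
#' @return Filtered series, same shape as the input.
#' @export
highpass <- function(series, sigma_s = 50, TR_s = 3) {
  stop_if_not_scalar_number(sigma_s, "sigma_s")
  if (sigma_s <= 0) stop("sigma_s must be > 0", call. = FALSE)
  S <- highpass_matrix(if (is.matrix(series)) nrow(series) else length(series),
                       sigma_s, TR_s)
  if (is.matrix(series)) {
    res <- series - S %*% series
    sweep(res, 2, colMeans(series), "+")
  } else {
    as.numeric(series - S %*% series + mean(series))
  }
}

# Smoother matrix of the Gaussian-weighted local line fit: row i gives the
# weights producing the fitted value at time i. O(n^2) build, reused across
# voxels by passing matrices to highpass().
highpass_matrix <- function(n, sigma_s, TR_s) {
  if (n < 3) stop("series length must be >= 3", call. = FALSE)
  t <- (seq_len(n) - 1) * TR_s
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- exp(-0.5 * ((t - t[i]) / sigma_s)^2)
    w <- w / sum(w)
    tb <- sum(w * t)
    d <- t - tb
    denom <- sum(w * d^2)
    # fitted value at t[i] of the weighted line: wls intercept + slope * t[i]
    S[i, ] <- w + (t[i] - tb) * (w * d) / denom
  }
  S
}
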