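# Block schedule, HRF, regressors and high-pass filtering.

test_that("block schedule has the localiser structure", {
  sched <- std_schedule
  expect_equal(nrow(sched), 40L)
  expect_equal(sched$position[sched$condition == "fixation"],
               c(1L, 14L, 27L, 40L))
  counts <- table(sched$condition)
  expect_equal(unname(counts[c("scenes", "objects", "scrambled")]),
               rep(12L, 3), ignore_attr = TRUE)
  expect_equal(schedule_duration(sched), 640)
  # contiguous, strictly increasing onsets
  expect_equal(sched$onset_s, (0:39) * 16)
  expect_true(all(sched$duration_s == 16))
  # 36 experimental blocks = 3 orders x 4 repeats x 3 blocks
  expect_equal(sum(sched$condition != "fixation"), 36L)
})

test_that("double-gamma HRF starts at zero, peaks in 4.5-6.5 s, undershoots", {
  h <- double_gamma_hrf()
  expect_equal(h$samples[1], 0)
  imax <- which.max(h$samples)
  expect_gte(h$t_s[imax], 4.5)
  expect_lte(h$t_s[imax], 6.5)
  expect_equal(max(h$samples), 1)                       # unit peak
  expect_equal(sum(h$samples == max(h$samples)), 1L)    # unique maximum
  after <- h$samples[imax:length(h$samples)]
  expect_lt(min(after), 0)                              # undershoot
  expect_lt(imax, which.min(h$samples))                 # max precedes min
  expect_error(double_gamma_hrf(dt_s = 0), "dt_s")
  expect_error(double_gamma_hrf(length_s = 20), "length_s")
})

test_that("regressors convolve the boxcar and sample at volume times", {
  hrf <- double_gamma_hrf()
  # single 16-s block: peak after onset, before onset + 24 s
  one <- data.frame(position = 1, condition = "scenes", onset_s = 32,
                    duration_s = 16)
  class(one) <- c("block_schedule", "data.frame")
  r <- make_regressor(one, "scenes", hrf, TR_s = 3, n_volumes = 40)
  tmax <- (which.max(r) - 1) * 3
  expect_gt(tmax, 32)
  expect_lt(tmax, 32 + 24)
  # direct-summation convolution oracle at the volume times
  t_vol <- (0:39) * 3
  oracle <- vapply(t_vol, function(tt) {
    tau <- seq(0, 32, by = hrf$dt_s)
    box <- as.numeric(tt - tau >= 32 & tt - tau < 48)
    sum(hrf$samples[seq_along(tau)] * box) * hrf$dt_s
  }, numeric(1))
  expect_equal(as.numeric(r), oracle, tolerance = 0.02)

  # absent condition of a known label -> all-zero regressor
  r0 <- make_regressor(one, "objects", hrf, TR_s = 3, n_volumes = 40)
  expect_true(all(r0 == 0))
  expect_equal(attr(r0, "height"), 0)
  expect_error(make_regressor(one, "faces", hrf, TR_s = 3, n_volumes = 40),
               "unknown condition")

  # linearity: two blocks = sum of the single-block regressors
  two <- data.frame(position = 1:2, condition = "scenes",
                    onset_s = c(32, 128), duration_s = 16)
  class(two) <- c("block_schedule", "data.frame")
  oneb <- data.frame(position = 1, condition = "scenes", onset_s = 128,
                     duration_s = 16)
  class(oneb) <- c("block_schedule", "data.frame")
  r2 <- make_regressor(two, "scenes", hrf, TR_s = 3, n_volumes = 60)
  ra <- make_regressor(one, "scenes", hrf, TR_s = 3, n_volumes = 60)
  rb <- make_regressor(oneb, "scenes", hrf, TR_s = 3, n_volumes = 60)
  expect_equal(as.numeric(r2), as.numeric(ra) + as.numeric(rb),
               tolerance = 1e-10)
})

test_that("design matrix has one regressor per condition plus constant", {
  X <- build_design_matrix(std_schedule, apply_highpass = FALSE)
  expect_equal(nrow(X$X), 214L)
  expect_equal(colnames(X$X), c("scenes", "objects", "scrambled", "constant"))
  expect_equal(sum(colnames(X$X) == "constant"), 1L)
  # condition columns are zero before the condition's first response onset
  for (cc in c("scenes", "objects", "scrambled")) {
    first_onset <- min(std_schedule$onset_s[std_schedule$condition == cc])
    before <- which((seq_len(214) - 1) * 3 < first_onset)
    expect_true(all(X$X[before, cc] == 0))
  }
  expect_true(all(X$heights > 0))
})

test_that("regressor construction commutes with block-order permutation", {
  # swapping the roles of the other conditions leaves a condition's
  # regressor unchanged wherever its own blocks are unchanged
  sched2 <- std_schedule
  sw <- sched2$condition == "objects"
  sched2$condition[sched2$condition == "scrambled"] <- "objects"
  sched2$condition[sw] <- "scrambled"
  hrf <- double_gamma_hrf()
  r1 <- make_regressor(std_schedule, "scenes", hrf, 3, 214)
  r2 <- make_regressor(sched2, "scenes", hrf, 3, 214)
  expect_identical(as.numeric(r1), as.numeric(r2))
})

test_that("high-pass removes slow trends and preserves fast components", {
  n <- 214
  expect_error(highpass(rnorm(n), sigma_s = 0), "sigma_s")
  # constant series unchanged
  cst <- rep(7, n)
  expect_equal(highpass(cst, 50, 3), cst, tolerance = 1e-12)
  # pure linear ramp -> grand mean everywhere
  ramp <- seq(0, 10, length.out = n)
  hp <- highpass(ramp, 50, 3)
  expect_lt(max(abs(hp - mean(ramp))), 1e-6 * diff(range(ramp)))
  # 32-s sinusoid (well above the cutoff frequency) passes nearly intact
  t <- (seq_len(n) - 1) * 3
  s32 <- sin(2 * pi * t / 32)
  expect_gte(diff(range(highpass(s32, 50, 3))), 0.9 * diff(range(s32)))
  # linearity on mean-zero inputs
  set.seed(4)
  x <- rnorm(n); x <- x - mean(x)
  y <- rnorm(n); y <- y - mean(y)
  expect_equal(highpass(2 * x + 3 * y, 50, 3),
               2 * highpass(x, 50, 3) + 3 * highpass(y, 50, 3),
               tolerance = 1e-10)
})

test_that("trial timing reconstructs the trials-per-block count", {
  expect_equal(trials_per_block(16, 200, 800), 16L)
  expect_equal(trials_per_block(16, 1000, 1000), 8L)
})
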