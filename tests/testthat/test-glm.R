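# Voxel-wise GLM, contrast Z maps, smoothing, percent signal change.

test_that("GLM interpolates a noiseless design combination exactly", {
  X <- std_design
  y <- 5 * X$X[, "scenes"] + 100
  Y <- cbind(y, y, y)
  fit <- fit_glm(Y, X)
  expect_true(all(abs(fit$betas["scenes", ] - 5) < 1e-8))
  expect_true(all(abs(fit$betas["constant", ] - 100) < 1e-8))
})

test_that("GLM matches the brute-force normal-equations oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:8, 1)
    p <- sample(2:min(4, n - 1), 1)
    X <- cbind(matrix(rnorm(n * (p - 1)), n), 1)
    colnames(X) <- c(paste0("c", seq_len(p - 1)), "constant")
    Y <- matrix(rnorm(n * 5), n, 5)
    fit <- fit_glm(Y, X)
    for (v in 1:5) {
      o <- ols_oracle(X, Y[, v])
      expect_lt(max(abs(fit$betas[, v] - o$beta)), 1e-10)
      expect_lt(abs(fit$sigma2[v] - o$sigma2), 1e-10)
    }
  }
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- cbind(a = std_design$X[, 1], b = std_design$X[, 1], constant = 1)
  expect_error(fit_glm(matrix(rnorm(214 * 2), 214), X), "collinear")
  expect_error(fit_glm(matrix(rnorm(10), 5), std_design), "match")
})

test_that("contrast Z maps: degenerate voxels, symmetry, calibration", {
  X <- std_design
  set.seed(21)
  Y <- cbind(matrix(rnorm(214 * 9999), 214), 7)  # last voxel constant
  fit <- fit_glm(Y, X)
  zm <- contrast_zmap(fit, "scenes>objects")
  # constant voxel: sigma2 = 0 and Z defined as 0
  expect_equal(fit$sigma2[10000], 0)
  expect_equal(zm$data[10000], 0)
  expect_true(all(is.finite(zm$data)))
  # exact anti-symmetry with the reversed contrast
  zr <- contrast_zmap(fit, "objects>scenes")
  expect_equal(zm$data, -zr$data, tolerance = 1e-12)
  # null calibration over ~10,000 voxels
  z <- zm$data[1:9999]
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.1)
  expect_error(contrast_zmap(fit, contrast_spec("scenes>scenes")), "contrast")
})

test_that("t-to-z mapping stays finite and tail-matched at large t", {
  expect_equal(t_to_z(0, 10), 0)
  z <- t_to_z(c(-40, 40), 210)
  expect_true(all(is.finite(z)))
  expect_equal(z[1], -z[2])
  # tail probability is preserved
  expect_equal(pnorm(t_to_z(2.5, 30), lower.tail = FALSE),
               pt(2.5, 30, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Gaussian smoothing is normalised, identity at 0, mass-conserving", {
  space <- tiny_space(16L)
  vol <- array(rnorm(16^3), dim = rep(16, 3))
  expect_identical(smooth_volume(vol, 0, 2), vol)
  expect_error(smooth_volume(vol, -1, 2), "fwhm")
  imp <- array(0, dim = rep(16, 3))
  imp[8, 8, 8] <- 1
  sm <- smooth_volume(imp, 5, 2)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  # impulse-response second moment matches sigma^2 within 2%
  xs <- (seq_len(16) - 8) * 2
  m2 <- sum(sm * outer(outer(xs^2, rep(1, 16)), rep(1, 16)))
  expect_lt(abs(m2 - fwhm_to_sigma(5)^2) / fwhm_to_sigma(5)^2, 0.02)
  # max is non-increasing in fwhm
  maxes <- vapply(c(0, 2, 5, 8), function(f)
    max(smooth_volume(imp, f, 2)), numeric(1))
  expect_true(all(diff(maxes) <= 1e-12))
})

test_that("percent signal change recovers planted amplitudes", {
  space <- small_space()
  # beta_condition == beta_scrambled -> 0%
  spec0 <- noiseless_spec(space, amplitude = 0, object_amplitude = 0)
  s0 <- generate_subject(spec0, 1)
  fit0 <- fit_subject_rois(s0)
  expect_equal(percent_signal_change(fit0, "scenes",
                                     s0$roi_masks$PHG), 0, tolerance = 1e-8)
  # planted 2% at the centre voxel recovers 2.0 within 0.2
  spec2 <- noiseless_spec(space, amplitude = 2)
  s2 <- generate_subject(spec2, 1)
  fit2 <- fit_subject_rois(s2)
  v <- round(mm_to_vox(space, s2$truth$center_mm$PHG))
  roi1 <- array(FALSE, dim = space$grid_shape)
  roi1[v[1], v[2], v[3]] <- TRUE
  psc2 <- percent_signal_change(fit2, "scenes", roi1)
  expect_lt(abs(psc2 - 2), 0.2)
  # doubling the planted amplitude doubles the PSC within 5%
  spec4 <- noiseless_spec(space, amplitude = 4)
  s4 <- generate_subject(spec4, 1)
  fit4 <- fit_subject_rois(s4)
  psc4 <- percent_signal_change(fit4, "scenes", roi1)
  expect_lt(abs(psc4 / psc2 - 2) / 2, 0.05)
  expect_error(percent_signal_change(fit2, "scenes", roi1, baseline_mean = -1),
               "baseline_mean")
})
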