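# ROI resampling, thresholding, connected components, peaks, long-axis split.

test_that("mask resampling: identity, translation, round trip", {
  space <- tiny_space(10L)
  m <- array(FALSE, dim = rep(10, 3))
  m[4:6, 4:6, 4:6] <- TRUE
  expect_identical(to_subject_space(m, diag(4), space), m)
  # pure translation by one voxel shifts by exactly one voxel
  A <- diag(4); A[1, 4] <- space$voxel_size   # template = subject + 2mm in x
  shifted <- to_subject_space(m, A, space)
  expect_identical(shifted[3:5, 4:6, 4:6], m[4:6, 4:6, 4:6])
  expect_equal(sum(shifted), sum(m))          # count preserved
  # round trip with the same affine is the identity for in-grid masks
  back <- map_to_template(shifted, A, space)
  expect_identical(back, m)
  expect_error(to_subject_space(m, matrix(0, 4, 4), space), "singular")
  far <- diag(4); far[1, 4] <- 1000
  expect_error(to_subject_space(m, far, space, roi_name = "PHG"), "PHG")
})

test_that("thresholding is strict, one-sided and nested", {
  space <- tiny_space()
  z0 <- as_zmap(array(0, dim = rep(8, 3)), space)
  expect_equal(sum(threshold_zmap(z0, threshold_spec(2.3))$data), 0)
  set.seed(3)
  arr <- array(rnorm(8^3, 0, 2), dim = rep(8, 3))
  zm <- as_zmap(arr, space)
  b23 <- threshold_zmap(zm, threshold_spec(2.3))$data
  b31 <- threshold_zmap(zm, threshold_spec(3.1))$data
  b39 <- threshold_zmap(zm, threshold_spec(3.9))$data
  expect_true(all(b39 <= b31) && all(b31 <= b23))   # nested
  # single voxel at 3.5: present at 2.3 and 3.1, absent at 3.9
  arr1 <- array(0, dim = rep(8, 3)); arr1[4, 4, 4] <- 3.5
  z1 <- as_zmap(arr1, space)
  expect_equal(sum(threshold_zmap(z1, threshold_spec(2.3))$data), 1)
  expect_equal(sum(threshold_zmap(z1, threshold_spec(3.1))$data), 1)
  expect_equal(sum(threshold_zmap(z1, threshold_spec(3.9))$data), 0)
  # boundary is excluded (strict inequality)
  arr1[4, 4, 4] <- 2.3
  expect_equal(sum(threshold_zmap(as_zmap(arr1, space),
                                  threshold_spec(2.3))$data), 0)
  expect_error(threshold_zmap(as_zmap(arr, space, fwhm = 5),
                              threshold_spec(2.3, fwhm = 0)), "mismatch")
  expect_error(threshold_spec(0), "z_threshold")
})

test_that("connected components respect the connectivity scheme", {
  b <- array(FALSE, dim = c(6, 6, 6))
  b[2, 2, 2] <- TRUE
  cs <- find_clusters(b)
  expect_equal(cs$n_clusters, 1L)
  expect_equal(cs$sizes, 1L)
  # two voxels sharing only a corner: one cluster at 26, two at 6
  b[3, 3, 3] <- TRUE
  expect_equal(find_clusters(b, 26)$n_clusters, 1L)
  expect_equal(find_clusters(b, 6)$n_clusters, 2L)
  # edge-sharing pair: joined at 18, separate at 6
  b2 <- array(FALSE, dim = c(6, 6, 6))
  b2[2, 2, 2] <- TRUE; b2[3, 3, 2] <- TRUE
  expect_equal(find_clusters(b2, 18)$n_clusters, 1L)
  expect_equal(find_clusters(b2, 6)$n_clusters, 2L)
  # sizes partition the suprathreshold set
  set.seed(8)
  b3 <- array(runif(6^3) < 0.2, dim = c(6, 6, 6))
  cs3 <- find_clusters(b3)
  expect_equal(sum(cs3$sizes), sum(b3))
  expect_equal(sort(unique(as.integer(cs3$labels[cs3$labels > 0]))),
               seq_len(cs3$n_clusters))
})

test_that("roi_has_activation intersects map and ROI strictly", {
  space <- tiny_space()
  arr <- array(0, dim = rep(8, 3)); arr[2, 2, 2] <- 5
  zm <- as_zmap(arr, space)
  roi <- array(FALSE, dim = rep(8, 3)); roi[5:7, 5:7, 5:7] <- TRUE
  res <- roi_has_activation(zm, roi, threshold_spec(2.3))
  expect_false(res$active)                 # suprathreshold voxel outside roi
  roi2 <- roi; roi2[2, 2, 2] <- TRUE
  for (thr in c(2.3, 3.1, 3.9)) {
    r <- roi_has_activation(zm, roi2, threshold_spec(thr))
    expect_true(r$active)
    expect_equal(r$n_voxels, 1L)
  }
  expect_error(roi_has_activation(zm, array(FALSE, dim = rep(8, 3)),
                                  threshold_spec(2.3)), "empty ROI")
  expect_error(roi_has_activation(zm, roi, threshold_spec(2.3),
                                  roi_space_tag = "template"), "space")
})

test_that("peak_in_roi matches a brute-force scan and breaks ties by raster", {
  space <- tiny_space()
  # deterministic tie-break: two equal maxima -> earlier raster voxel
  arr <- array(0, dim = rep(8, 3))
  arr[5, 5, 5] <- 4; arr[2, 3, 6] <- 4
  roi <- array(TRUE, dim = rep(8, 3))
  pk <- peak_in_roi(as_zmap(arr, space), roi)
  expect_equal(c(pk$x_mm, pk$y_mm, pk$z_mm),
               vox_to_mm(space, c(5, 5, 5)))  # linear index of (5,5,5) is lower
  set.seed(13)
  for (rep in 1:100) {
    arr <- array(rnorm(6^3), dim = c(6, 6, 6))
    roi <- array(runif(6^3) < 0.4, dim = c(6, 6, 6))
    if (!any(roi)) next
    sp6 <- tiny_space(6L)
    pk <- peak_in_roi(as_zmap(arr, sp6), roi)
    # brute-force scan in raster order
    idx <- which(roi)
    best <- idx[which.max(arr[idx])]
    expect_equal(c(pk$x_mm, pk$y_mm, pk$z_mm),
                 vox_to_mm(sp6, as.numeric(arrayInd(best, dim(arr)))))
    expect_equal(pk$peak_z, arr[best])
  }
  expect_error(peak_in_roi(as_zmap(array(0, dim = rep(8, 3)), space),
                           array(FALSE, dim = rep(8, 3))), "empty ROI")
})

test_that("hippocampal long-axis split follows the documented convention", {
  expect_equal(split_hc_long_axis(c(22, -16, -22), -21), "anterior")
  expect_equal(split_hc_long_axis(c(22, -21, -22), -21), "anterior")  # boundary
  expect_equal(split_hc_long_axis(c(22, -31, -22), -21), "posterior")
  space <- small_space()
  rois <- make_template_rois(space)
  expect_error(split_hc_long_axis(c(0, 0, 0), -21, rois$masks$HC, space),
               "outside")
  inside <- roi_consensus_centers()$HC
  expect_equal(split_hc_long_axis(inside, -21, rois$masks$HC, space),
               "anterior")
})
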