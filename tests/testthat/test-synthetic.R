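# Template ROIs and the synthetic cohort generator.

test_that("template ROIs are non-empty, disjoint and bilaterally mirrored", {
  for (space in list(template_space(), small_space())) {
    rois <- make_template_rois(space)
    counts <- vapply(rois$masks, sum, numeric(1))
    expect_true(all(counts > 0))
    total <- Reduce(`+`, lapply(rois$masks, function(m) m * 1L))
    expect_lte(max(total), 1L)   # pairwise disjoint
    # mirrored in x: for every in-mask voxel the x-mirrored voxel is in-mask
    for (m in rois$masks) {
      co <- vox_to_mm(space, arrayInd(which(m), dim(m)))
      co[, 1] <- -co[, 1]
      vi <- round(mm_to_vox(space, co))
      expect_true(all(m[vi]))
    }
  }
  # HC straddles the long-axis split
  rois <- make_template_rois(small_space())
  ys <- small_space()$origin_mm[2] + (seq_len(36) - 1) * 2
  hc_y <- ys[apply(rois$masks$HC, 2, any)]
  expect_true(any(hc_y >= rois$hc_split_y_mm))
  expect_true(any(hc_y < rois$hc_split_y_mm))
  expect_error(make_template_rois(template_space(c(8, 8, 8))), "grid too small")
})

test_that("consensus centres lie inside their ROI masks", {
  space <- small_space()
  rois <- make_template_rois(space)
  ctr <- roi_consensus_centers()
  for (rn in names(ctr)) {
    v <- round(mm_to_vox(space, ctr[[rn]]))
    expect_true(rois$masks[[rn]][v[1], v[2], v[3]], label = rn)
  }
})

test_that("subject centres are jittered, clamped in-ROI and seeded", {
  space <- small_space()
  rois <- make_template_rois(space)
  ctr <- roi_consensus_centers()$PHG
  # zero jitter returns the consensus exactly
  expect_identical(sample_subject_center(ctr, 0, rois$masks$PHG, space, 1), ctr)
  # determinism and in-ROI clamping
  draws <- t(vapply(1:50, function(s)
    sample_subject_center(ctr, 6, rois$masks$PHG, space, s), numeric(3)))
  draws2 <- t(vapply(1:50, function(s)
    sample_subject_center(ctr, 6, rois$masks$PHG, space, s), numeric(3)))
  expect_identical(draws, draws2)
  for (i in seq_len(nrow(draws))) {
    v <- round(mm_to_vox(space, draws[i, ]))
    expect_true(rois$masks$PHG[v[1], v[2], v[3]])
  }
  expect_error(sample_subject_center(ctr, 2, array(FALSE, space$grid_shape),
                                     space, 1), "empty ROI")
})

test_that("jitter SD is recovered in a large ROI (Monte-Carlo)", {
  space <- small_space()
  big <- array(TRUE, dim = space$grid_shape)   # effectively unbounded ROI
  ctr <- c(0, 0, 0)
  draws <- t(vapply(1:1000, function(s)
    sample_subject_center(ctr, 4, big, space, s), numeric(3)))
  sds <- apply(draws, 2, sd)
  expect_true(all(abs(sds - 4) / 4 < 0.15))
})

test_that("noise-free zero-amplitude BOLD is constant baseline", {
  space <- small_space()
  spec <- noiseless_spec(space, amplitude = 0)
  s <- generate_subject(spec, 1)
  expect_equal(max(abs(s$bold$data - spec$baseline)), 0)
  expect_equal(nrow(s$bold$data), 214L)
})

test_that("BOLD generation is bit-identical for equal seeds", {
  truth <- subject_truth(1, roi_consensus_centers(), 3, 1.5, 0, 50, 10)
  b1 <- generate_subject_bold(truth, std_schedule, small_space(), seed = 9)
  b2 <- generate_subject_bold(truth, std_schedule, small_space(), seed = 9)
  expect_identical(b1$data, b2$data)
  b3 <- generate_subject_bold(truth, std_schedule, small_space(), seed = 10)
  expect_false(identical(b1$data, b3$data))
  bad <- truth
  bad$affine_subject_to_template <- matrix(0, 4, 4)
  expect_error(generate_subject_bold(bad, std_schedule, small_space(), 1),
               "affine")
})

test_that("no-noise planted beta matches the closed-form projection", {
  space <- small_space()
  spec <- noiseless_spec(space, amplitude = 2)
  s <- generate_subject(spec, 1)
  fit <- fit_subject_rois(s)
  ctr <- s$truth$center_mm$PHG
  v <- round(mm_to_vox(space, ctr))
  lin <- v[1] + (v[2] - 1) * 30 + (v[3] - 1) * 30 * 36
  beta <- fit$betas["scenes", match(lin, fit$voxels)]
  predicted <- spec$baseline * 0.02 / std_design$heights[["scenes"]]
  expect_lt(abs(beta - predicted) / predicted, 0.01)
})

test_that("cohort generation is deterministic and respects the affine", {
  space <- small_space()
  rois <- make_template_rois(space)
  spec <- cohort_spec(n_subjects = 3, base_seed = 3, space = space,
                      rois = rois, max_shift_mm = 0, noise_sd = 10)
  co <- generate_cohort(spec, keep_bold = FALSE)
  # zero shift: subject masks identical to the template masks
  for (s in co$subjects) {
    expect_identical(s$truth$affine_subject_to_template, diag(4))
    for (rn in names(rois$masks)) {
      expect_identical(s$roi_masks[[rn]], rois$masks[[rn]] == TRUE)
    }
  }
  # same base_seed -> identical truth records
  truths2 <- cohort_truths(spec)
  for (i in 1:3) expect_identical(co$subjects[[i]]$truth, truths2[[i]])
})

test_that("every subject's scene centres fall inside their ROIs", {
  space <- small_space()
  rois <- make_template_rois(space)
  spec <- cohort_spec(n_subjects = 20, base_seed = 17, space = space,
                      rois = rois)
  for (truth in cohort_truths(spec)) {
    for (rn in names(rois$masks)) {
      v <- round(mm_to_vox(space, truth$center_mm[[rn]]))
      expect_true(rois$masks[[rn]][v[1], v[2], v[3]],
                  label = sprintf("subject %d %s", truth$subject_id, rn))
    }
  }
})
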