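# Group one-sample inference, permutation cluster-extent control, and the
# cohort summary statistics.

test_that("group one-sample Z matches the closed-form toy and is symmetric", {
  d <- c(4, 4, 4)
  maps <- lapply(1:3, function(i) array(0, dim = d))
  maps[[1]][2, 2, 2] <- 1; maps[[2]][2, 2, 2] <- 2; maps[[3]][2, 2, 2] <- 3
  gz <- group_one_sample_z(maps)
  # values (1,2,3): mean 2, SE 0.577, t = 3.464, mapped through t->Z (df 2)
  t_exp <- 2 / (sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(t_exp, 3.464, tolerance = 1e-3)
  expect_equal(gz$data[2, 2, 2], t_to_z(t_exp, 2), tolerance = 1e-10)
  expect_equal(gz$data[1, 1, 1], 0)          # all-zero voxel
  neg <- group_one_sample_z(lapply(maps, function(m) -m))
  expect_equal(neg$data, -gz$data)           # exact anti-symmetry
  # zero between-subject variance -> capped, not infinite
  same <- lapply(1:3, function(i) array(1, dim = d))
  gz_cap <- group_one_sample_z(same)
  expect_true(all(gz_cap$data == 8.2))
  expect_error(group_one_sample_z(maps[1:2]), "3 subjects")
})

test_that("cluster-extent correction is deterministic and detects signal", {
  d <- c(12, 12, 12)
  set.seed(31)
  blob <- array(0, dim = d); blob[5:8, 5:8, 5:8] <- 2
  maps <- lapply(1:10, function(i) blob + array(rnorm(prod(d)), dim = d))
  r1 <- cluster_extent_correct(maps, n_perm = 119, seed = 77)
  r2 <- cluster_extent_correct(maps, n_perm = 119, seed = 77)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$mask, r2$mask)
  # a strong planted cluster survives correction
  expect_true(any(r1$significant))
  expect_true(all(r1$mask[6:7, 6:7, 6:7]))
  expect_error(cluster_extent_correct(maps, n_perm = 50, seed = 1), "n_perm")
})

test_that("planted group effects survive correction in almost all cohorts", {
  pw <- fwe_power_check(n_replicates = 20, n_subjects = 10, amplitude = 2,
                        seed = 19)
  expect_gte(pw$power, 0.95)
})

test_that("frequency table counts activating subjects per cell", {
  rec <- expand.grid(subject = 1:3, roi = c("PHG", "HC"),
                     z_threshold = c(2.3, 3.9), fwhm = 0,
                     stringsAsFactors = FALSE)
  rec$active <- c(TRUE, TRUE, TRUE,   # PHG z2.3
                  TRUE, FALSE, TRUE,  # HC z2.3
                  TRUE, FALSE, TRUE,  # PHG z3.9
                  FALSE, FALSE, TRUE) # HC z3.9
  ft <- frequency_table(rec)
  expect_equal(ft$proportion[ft$roi == "PHG" & ft$z_threshold == 2.3], 1.0)
  expect_equal(ft$proportion[ft$roi == "HC" & ft$z_threshold == 2.3], 2 / 3)
  expect_equal(ft$n_with_cluster[ft$roi == "PHG" & ft$z_threshold == 3.9], 2L)
  # nesting: proportions non-increasing in threshold
  for (rn in c("PHG", "HC")) {
    p <- ft$proportion[ft$roi == rn][order(ft$z_threshold[ft$roi == rn])]
    expect_true(all(diff(p) <= 0))
  }
  expect_error(frequency_table(rec, thresholds = c(2.3, 3.1)), "missing cells")
})

test_that("binomial preference scores scene>object with ties at 0", {
  psc <- rbind(
    data.frame(subject = 1, roi = "PHG", condition = "scenes", psc = 0.5),
    data.frame(subject = 1, roi = "PHG", condition = "objects", psc = 0.2),
    data.frame(subject = 2, roi = "PHG", condition = "scenes", psc = 0.3),
    data.frame(subject = 2, roi = "PHG", condition = "objects", psc = 0.3))
  b <- binomial_preference(psc)
  expect_equal(b["1", "PHG"], 1L)
  expect_equal(b["2", "PHG"], 0L)   # exact tie scores 0
  expect_error(binomial_preference(psc[-2, ]), "missing condition")
  # constructed 10-subject fixture: column means match hand counts
  set.seed(41)
  big <- do.call(rbind, lapply(1:10, function(s) {
    rbind(data.frame(subject = s, roi = "PHG", condition = "scenes",
                     psc = ifelse(s <= 7, 1, 0)),
          data.frame(subject = s, roi = "PHG", condition = "objects",
                     psc = 0.5))
  }))
  expect_equal(mean(binomial_preference(big)[, "PHG"]), 0.7)
})

test_that("Cochran's Q follows the defining sums with df = k - 1", {
  # identical columns -> Q = 0
  m <- matrix(rep(c(1, 0, 1, 0), 3), ncol = 3)
  expect_equal(cochrans_q(m)$Q, 0)
  # 4-subject x 3-region toy vs direct evaluation of the defining sums
  toy <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(1, 0, 0))
  res <- cochrans_q(toy)
  k <- 3; G <- colSums(toy); L <- rowSums(toy); Tt <- sum(toy)
  Q_oracle <- k * (k - 1) * sum((G - Tt / k)^2) / (k * sum(L) - sum(L^2))
  expect_equal(res$Q, Q_oracle)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(Q_oracle, 2, lower.tail = FALSE))
  # df for 4 regions is 3
  expect_equal(cochrans_q(cbind(toy, c(0, 1, 0, 1)))$df, 3L)
  # invariant under region-column permutation
  expect_equal(cochrans_q(toy[, c(3, 1, 2)])$Q, res$Q)
  # all rows constant: denominator 0 -> Q = 0, p = 1
  const <- rbind(c(1, 1, 1), c(0, 0, 0))
  expect_equal(cochrans_q(const)$Q, 0)
  expect_equal(cochrans_q(const)$p_value, 1)
  expect_error(cochrans_q(matrix(2, 3, 3)), "0 or 1")
})

test_that("paired effect matches hand computation and t.test", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)   # differences (1, 2, 3)
  pe <- paired_effect(a, b)
  expect_equal(pe$t, 3.464, tolerance = 1e-3)
  expect_equal(pe$cohen_d, 2.0)
  expect_equal(pe$t, unname(t.test(a, b, paired = TRUE)$statistic),
               tolerance = 1e-12)
  # scale invariance
  pe10 <- paired_effect(10 * a, 10 * b)
  expect_equal(pe10$t, pe$t)
  expect_equal(pe10$cohen_d, pe$cohen_d)
  # identical samples: zero effect, not an error
  expect_equal(paired_effect(a, a)$t, 0)
  # degenerate but non-zero differences are rejected
  expect_error(paired_effect(a, a - 1), "zero SD")
})
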