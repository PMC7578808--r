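grid16 <- function(n) build_frame_grid(n * 16, 16, 0)

test_that("ROI extraction averages voxels within labels", {
  # single ROI, every voxel equals its frame index
  arr <- array(rep(0:5, each = 4^3), dim = c(4, 4, 4, 6))
  parc1 <- parcellation(array(1L, c(4, 4, 4)))
  ts <- extract_roi_timeseries(dynamic_image(arr, grid16(6)), parc1)
  expect_equal(as.numeric(ts$values), 0:5)
  # two constant ROIs
  lab <- array(1L, c(4, 4, 4)); lab[3:4, , ] <- 2L
  arr2 <- array(3, dim = c(4, 4, 4, 5)); arr2[3:4, , , ] <- 5
  ts2 <- extract_roi_timeseries(dynamic_image(arr2, grid16(5)),
                                parcellation(lab))
  expect_equal(unname(ts2$values), rbind(rep(3, 5), rep(5, 5)))
  # random image equals the per-voxel loop oracle
  set.seed(31)
  lab3 <- array(sample(0:4, 6^3, replace = TRUE), c(6, 6, 6))
  lab3[1] <- 1L  # ensure ROI 1 nonempty
  arr3 <- array(rnorm(6^3 * 7), dim = c(6, 6, 6, 7))
  parc3 <- parcellation(lab3, roi_ids = 1:4)
  got <- extract_roi_timeseries(dynamic_image(arr3, grid16(7)), parc3)
  expect_equal(unname(got$values), oracle_roi_means(arr3, lab3, got$roi_ids))
  # shape mismatch rejected; empty ROI dropped with warning
  expect_error(extract_roi_timeseries(dynamic_image(arr2, grid16(5)), parc3),
               "incompatible")
  parc5 <- parcellation(lab3, roi_ids = 1:5)
  expect_warning(ts5 <- extract_roi_timeseries(
    dynamic_image(arr3, grid16(7)), parc5), "empty ROI")
  expect_equal(ts5$roi_ids, 1:4)
})

test_that("high-pass filtering removes drift and keeps fast signal", {
  n <- 225; tr <- 2.45
  tt <- (seq_len(n) - 0.5) * tr
  const <- roi_timeseries(matrix(7, 1, n), 1L, tt, tr)
  expect_equal(max(abs(highpass_fmri(const)$values)), 0, tolerance = 1e-10)
  # 0.1 Hz sinusoid passes with amplitude preserved within 5%
  sine <- sin(2 * pi * 0.1 * tt)
  hp <- highpass_fmri(roi_timeseries(rbind(sine), 1L, tt, tr))
  expect_equal(sd(hp$values), sd(sine), tolerance = 0.05)
  expect_equal(mean(hp$values), 0, tolerance = 1e-10)
  # linear drift is almost entirely removed
  drift <- seq(0, 10, length.out = n)
  hd <- highpass_fmri(roi_timeseries(rbind(drift), 1L, tt, tr))
  expect_lt(sd(hd$values), 0.05 * sd(drift))
  expect_error(highpass_fmri(const, cutoff_hz = 0.5), "Nyquist")
})

test_that("subject connectivity is a zeroed-diagonal Pearson matrix", {
  set.seed(12)
  x <- matrix(rnorm(5 * 50), 5, 50)
  x[2, ] <- x[1, ]            # duplicate row
  x[3, ] <- -x[1, ]           # negated row
  ts <- roi_timeseries(x, 1:5, (0:49) * 16 + 8, 16)
  m <- subject_connectivity(ts)
  expect_equal(m$values[1, 2], 1)
  expect_equal(m$values[1, 3], -1)
  expect_equal(diag(m$values), rep(0, 5))
  expect_equal(m$values, t(m$values))
  expect_true(all(abs(m$values) <= 1 + 1e-12))
  x[4, ] <- 2
  expect_error(subject_connectivity(
    roi_timeseries(x, 1:5, (0:49) * 16 + 8, 16)), "4")
})

test_that("group averaging works on the Fisher-z scale", {
  mk <- function(r) connectivity_matrix(matrix(c(0, r, r, 0), 2), 1:2)
  expect_equal(group_average(list(mk(0.5), mk(0.5)))$values[1, 2], 0.5)
  expect_equal(group_average(list(mk(0.8), mk(0.2)))$values[1, 2],
               tanh((atanh(0.8) + atanh(0.2)) / 2))
  expect_equal(group_average(list(mk(0.7)))$values, mk(0.7)$values)
  # plain averaging is available and differs for unequal inputs
  expect_equal(group_average(list(mk(0.8), mk(0.2)),
                             fisher = FALSE)$values[1, 2], 0.5)
  bad <- mk(0.3); bad$modality <- "fmri"
  expect_error(group_average(list(mk(0.3), bad)), "mixed modality")
  expect_equal(group_average(list(mk(0.5)))$aggregation, "group")
})

test_that("static image is the voxelwise frame sum", {
  ones <- dynamic_image(array(1, c(3, 3, 3, 225)),
                        build_frame_grid(5700, 16, 0),
                        frame_indices = 112:336)
  expect_true(all(static_image(ones) == 225))
  set.seed(5)
  arr <- array(rnorm(4^3 * 6), c(4, 4, 4, 6))
  img <- dynamic_image(arr, grid16(6))
  want <- arr[, , , 1] * 0
  for (t in 1:6) want <- want + arr[, , , t]
  expect_equal(static_image(img), want)
  one <- dynamic_image(arr[, , , 1, drop = FALSE], grid16(1))
  expect_equal(static_image(one), arr[, , , 1])
})

test_that("metabolic covariance correlates demeaned uptake across subjects", {
  set.seed(21)
  n_sub <- 200
  base <- rnorm(n_sub)
  m <- cbind(base, base + rnorm(n_sub, sd = 1e-8),
             matrix(rnorm(n_sub * 80), n_sub, 80))
  # demeaning happens internally; identical columns correlate at 1
  got <- metabolic_covariance(m + rnorm(n_sub))  # per-subject offsets
  expect_equal(got$values[1, 2], 1, tolerance = 1e-6)
  # invariance to per-subject additive offsets
  off <- metabolic_covariance(m + 13 * rnorm(n_sub))
  expect_equal(metabolic_covariance(m)$values, off$values, tolerance = 1e-6)
  # independent regional values: off-diagonals obey the null bound
  indep <- matrix(rnorm(n_sub * 82), n_sub, 82)
  r <- metabolic_covariance(indep)$values
  offd <- abs(r[upper.tri(r)])
  expect_gt(mean(offd < 0.14), 0.9)
  expect_error(metabolic_covariance(m[1:2, ]), "3 subjects")
})

test_that("block partition matches the midpoint rule for the study window", {
  acq <- tiny_acq()
  net <- tiny_net(seed = 13)
  ts <- simulate_roi_uptake(net, acq)
  bs <- block_stability(ts)
  expect_equal(bs$block_sizes, c(37L, 38L, 37L, 38L, 37L, 38L))
  expect_equal(sum(bs$block_sizes), 225L)
  expect_length(bs$block_matrices, 6L)
  expect_equal(bs$block_matrices[[3]]$block, 3)
  expect_true(all(is.finite(bs$similarity)))
  expect_error(block_stability(ts, n_blocks = 100), "3 frames|outside")
})

test_that("block similarity has no trend for stationary planted signal", {
  acq <- tiny_acq()
  net <- tiny_net()
  slopes <- sapply(1:100, function(s) {
    bs <- block_stability(simulate_roi_uptake(net, acq, seed = 300 + s))
    coef(lm(bs$similarity ~ seq_along(bs$similarity)))[2]
  })
  ci <- mean(slopes) + c(-1, 1) * 1.96 * sd(slopes) / 10
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("a late-emerging planted signal shows up in late blocks", {
  acq <- tiny_acq()
  net <- network_spec(n_roi = 8, n_communities = 2, rho_within = 0.8,
                      rho_between = 0, seed = 6)
  ts <- simulate_roi_uptake(net, acq, seed = 17)
  # suppress the correlated fluctuation in blocks 1-4: replace by
  # independent noise of the same scale
  anchor <- ts$frame_mid_s[1] - ts$frame_duration_s / 2
  early <- floor((ts$frame_mid_s - anchor) / 600) < 4
  set.seed(99)
  ts$values[, early] <- mean(ts$values) +
    matrix(rnorm(sum(early) * 8), 8, sum(early))
  bs <- block_stability(ts)
  expect_gt(mean(bs$similarity[5:6]), mean(bs$similarity[1:2]))
})
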