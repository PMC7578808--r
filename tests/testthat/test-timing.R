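test_that("frame grid reproduces the acquisition binning", {
  g <- build_frame_grid(5700, 16, 1800)
  expect_identical(g$n_frames, 356L)
  expect_equal(g$frame_start_s, (0:355) * 16)
  expect_equal(g$frame_mid_s, g$frame_start_s + 8)
  # partial trailing frame discarded
  expect_identical(build_frame_grid(5705, 16, 0)$n_frames, 356L)
  expect_identical(build_frame_grid(16, 16, 0)$n_frames, 1L)
  # last complete frame ends within the scan
  expect_lte(g$frame_start_s[g$n_frames] + g$frame_duration_s, 5700)
  expect_error(build_frame_grid(10, 16, 0), "exceeds")
  expect_error(build_frame_grid(5700, 16, 5700), "analysis_onset")
})

test_that("analysis window selects the retained frames", {
  g <- build_frame_grid(5700, 16, 1800)
  w <- analysis_window(g, 6, 600)
  expect_length(w, 225L)
  expect_identical(w[1], 112L)  # frame containing the 30-min onset
  expect_identical(analysis_window(build_frame_grid(100, 16, 0), 1, 16), 0L)
  g0 <- build_frame_grid(5700, 16, 0)
  expect_identical(analysis_window(g0, 1, 5700), 0:355)
  expect_error(analysis_window(g, 7, 600), "beyond the scan")
})

test_that("decay correction matches the closed form", {
  expect_equal(decay_correct(240, 240, 0), 1)           # rate unchanged
  expect_equal(decay_correct(240, 240, 6586.2), 2)      # one half-life
  expect_equal(decay_correct(100, 60, 1800, 6586.2),
               (100 / 60) * 2^(1800 / 6586.2))
  # multiplicative and monotone increasing in elapsed time
  el <- seq(0, 5000, by = 500)
  f <- decay_correct(1, 1, el)
  expect_true(all(diff(f) > 0))
  expect_equal(decay_correct(7, 3, el), 7 / 3 * f)
  expect_error(decay_correct(10, 60, 100, -1), "half_life")
  expect_error(decay_correct(10, 0, 100), "count_duration")
})

test_that("quadratic plasma fit recovers exact and random instances", {
  t <- seq(600, 5400, by = 600)
  y <- 2 + 3 * t - 0.01 * t^2
  fit <- fit_plasma_curve(data.frame(draw_time_s = t, activity = y))
  expect_equal(fit$c0, 2, tolerance = 1e-9)
  expect_equal(fit$c1, 3, tolerance = 1e-9)
  expect_equal(fit$c2, -0.01, tolerance = 1e-9)
  expect_identical(fit$n_samples_used, length(t))

  expect_error(fit_plasma_curve(data.frame(draw_time_s = t[1:2],
                                           activity = y[1:2])),
               ">= 3 samples")
  expect_error(fit_plasma_curve(data.frame(draw_time_s = c(1, 1, 1, 2),
                                           activity = 1:4)),
               ">= 3 samples|collinear")

  # equals the normal-equations oracle on random instances
  set.seed(42)
  for (i in 1:20) {
    tt <- sort(runif(10, 0, 5700))
    yy <- rnorm(10, sd = 5) + runif(1, 0, 50) + runif(1, -0.01, 0.05) * tt
    got <- fit_plasma_curve(data.frame(draw_time_s = tt, activity = yy))
    want <- oracle_quadfit(tt, yy)
    expect_equal(c(got$c0, got$c1, got$c2), unname(want), tolerance = 1e-8)
  }
})

test_that("noisy quadratic fits are unbiased over repeated draws", {
  t <- seq(600, 5700, by = 600)
  truth <- c(5, 0.04, -4e-6)
  set.seed(7)
  est <- replicate(500, {
    y <- truth[1] + truth[2] * t + truth[3] * t^2 + rnorm(length(t), sd = 2)
    f <- fit_plasma_curve(data.frame(draw_time_s = t, activity = y))
    c(f$c0, f$c1, f$c2)
  })
  bias <- rowMeans(est) - truth
  # Monte-Carlo error bound: 4 SEs of each coefficient estimate
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias) < 4 * se + 1e-12))
})

test_that("group plasma curve is the pointwise mean of the fits", {
  grid <- seq(0, 5400, by = 600)
  c1 <- fit_plasma_curve(data.frame(draw_time_s = c(0, 1000, 2000, 3000),
                                    activity = c(0, 10, 18, 24)))
  expect_equal(group_average_curve(list(c1), grid)$activity,
               predict_plasma_curve(c1, grid))
  expect_equal(group_average_curve(list(c1, c1), grid)$activity,
               predict_plasma_curve(c1, grid))
  # y = t and y = -t average to zero
  up <- fit_plasma_curve(data.frame(draw_time_s = 0:3, activity = 0:3))
  dn <- fit_plasma_curve(data.frame(draw_time_s = 0:3, activity = -(0:3)))
  expect_equal(group_average_curve(list(up, dn), grid)$activity,
               rep(0, length(grid)), tolerance = 1e-10)
  expect_error(group_average_curve(list(), grid), "at least one")
})

test_that("blood-sample tables round-trip through TSV", {
  acq <- tiny_acq()
  s <- simulate_plasma_input(acq, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blood_samples(s, f)
  back <- read_blood_samples(f)
  expect_equal(back$raw_counts, s$raw_counts, tolerance = 1e-12)
  expect_equal(back$draw_time_s, s$draw_time_s)
})
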