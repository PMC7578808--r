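test_that("plasma samples rise to the 90-min peak and honour the seed", {
  acq <- acquisition_spec()
  s <- simulate_plasma_input(acq, peak_time_s = 5400, noise_cv = 0)
  expect_true(all(diff(s$activity[s$draw_time_s <= 5400]) > 0))
  # noiseless samples sit exactly on the quadratic; downstream fit
  # recovers it through the raw-count + decay-correction path
  s$activity <- decay_correct(s$raw_counts, s$count_duration_s,
                              s$draw_time_s)
  fit <- fit_plasma_curve(s)
  expect_equal(predict_plasma_curve(fit, s$draw_time_s), s$activity,
               tolerance = 1e-9)
  # seeds affect only the noise
  a <- simulate_plasma_input(acq, seed = 1)
  b <- simulate_plasma_input(acq, seed = 2)
  expect_false(isTRUE(all.equal(a$activity, b$activity)))
  expect_equal(simulate_plasma_input(acq, seed = 1), a)
  expect_error(simulate_plasma_input(acq, peak_time_s = 300), "precedes")
  expect_error(simulate_plasma_input(acq, peak_time_s = 9000), "within")
})

test_that("simulated uptake rates carry the planted correlation", {
  acq <- tiny_acq()
  # independent ROIs: sample correlations near zero at 225 frames
  net0 <- network_spec(n_roi = 8, rho_within = 0, rho_between = 0, seed = 4)
  r0 <- simulate_roi_uptake(net0, acq)
  expect_equal(ncol(r0$values), 225L)
  cc <- cor(t(r0$values))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
  # determinism
  expect_equal(simulate_roi_uptake(net0, acq), r0)
  expect_false(isTRUE(all.equal(
    simulate_roi_uptake(net0, acq, seed = 99)$values, r0$values)))
  # rates are nonnegative
  expect_true(all(r0$values >= 0))
  # a correlation pattern that is not positive semi-definite is rejected
  expect_error(network_spec(n_roi = 9, n_communities = 3, rho_within = 0,
                            rho_between = 0.9), "positive semi-definite")
})

test_that("planted within-community correlation is recovered without bias", {
  acq <- tiny_acq()
  net <- network_spec(n_roi = 8, n_communities = 2, rho_within = 0.6,
                      rho_between = 0)
  masks <- community_masks(net$block_assignment)
  mean_within <- mean(sapply(1:200, function(s) {
    r <- simulate_roi_uptake(net, acq, seed = s)
    mean(cor(t(r$values))[masks$within])
  }))
  expect_equal(mean_within, 0.6, tolerance = 0.02)
})

test_that("cumulative integration is the inverse of differencing", {
  acq <- tiny_acq()
  net <- tiny_net(seed = 8)
  rates <- simulate_roi_uptake(net, acq)
  cum <- integrate_cumulative(rates)
  # monotone nondecreasing per ROI
  expect_true(all(apply(cum$values, 1, function(v) all(diff(v) >= 0))))
  # first differences / frame duration reproduce the rates
  rec <- cbind(cum$values[, 1], t(apply(cum$values, 1, diff))) /
    rates$frame_duration_s
  expect_equal(rec, rates$values, tolerance = 1e-12, ignore_attr = TRUE)
  # constant rate a: cumulative at frame k is a (k+1) dt
  const <- roi_timeseries(matrix(3, 1, 5), 1L, (0:4) * 16 + 8, 16)
  expect_equal(as.numeric(integrate_cumulative(const)$values),
               3 * (1:5) * 16)
  zero <- roi_timeseries(matrix(0, 2, 5), 1:2, (0:4) * 16 + 8, 16)
  expect_true(all(integrate_cumulative(zero)$values == 0))
  neg <- roi_timeseries(matrix(-1, 1, 5), 1L, (0:4) * 16 + 8, 16)
  expect_error(integrate_cumulative(neg), "nonnegative")
})

test_that("volume rendering paints, blurs and perturbs ROI time courses", {
  net <- network_spec(n_roi = 6, n_communities = 2, seed = 5)
  acq <- acquisition_spec(grid_shape = c(12, 12, 12), psf_fwhm_mm = 0,
                          noise_sd = 0)
  parc <- synthetic_parcellation(c(12, 12, 12), 6)
  rates <- simulate_roi_uptake(net, acq,
                               frames = analysis_window(acq_frame_grid(acq))[1:20])
  cum <- integrate_cumulative(rates)
  # noiseless, unblurred: every in-ROI voxel equals its ROI TAC exactly
  img <- render_volumes(cum, parc, acq, seed = 1)
  v <- img$data[3, 3, 3, ]
  expect_equal(v, cum$values[parc$labels[3, 3, 3], ], ignore_attr = TRUE)
  # blur preserves monotonicity of ROI means
  acq_b <- acquisition_spec(grid_shape = c(12, 12, 12), psf_fwhm_mm = 5,
                            noise_sd = 0)
  ts_b <- extract_roi_timeseries(render_volumes(cum, parc, acq_b, seed = 1),
                                 parc)
  expect_true(all(apply(ts_b$values, 1, function(x) all(diff(x) >= 0))))
  # background voxels carry noise of the configured SD (10% on a 20^3 grid)
  acq_n <- acquisition_spec(grid_shape = c(20, 20, 20), psf_fwhm_mm = 0,
                            noise_sd = 2)
  parc_m <- synthetic_parcellation(c(20, 20, 20), 6, margin = 5)
  rates20 <- simulate_roi_uptake(net, acq_n,
                                 frames = analysis_window(acq_frame_grid(acq_n))[1:30])
  img_n <- render_volumes(integrate_cumulative(rates20), parc_m, acq_n,
                          seed = 77)
  bg <- which(parc_m$labels == 0L)[1:2000]
  m <- matrix(img_n$data, 20^3, 30)[bg, ]
  expect_equal(mean(apply(m, 1, sd)), 2, tolerance = 0.1)
  # mismatched grids are rejected
  expect_error(render_volumes(cum, parc_m, acq, seed = 1), "shape")
})

test_that("motion traces are random walks starting at the origin", {
  acq <- tiny_acq()
  tr0 <- simulate_motion(acq, step_sd_mm = 0, step_sd_rad = 0, seed = 1)
  expect_equal(nrow(tr0), 225L)
  expect_true(all(tr0 == 0))
  expect_equal(mean_relative_displacement(tr0), 0)
  tr <- simulate_motion(acq, seed = 3)
  expect_true(all(tr[1, ] == 0))
  expect_equal(simulate_motion(acq, seed = 3), tr)
  # constant x-step of 0.1 mm gives mean relative displacement 0.1
  inj <- tr0
  inj[, "x"] <- 0.1 * (seq_len(nrow(inj)) - 1)
  expect_equal(mean_relative_displacement(inj), 0.1)
  expect_error(simulate_motion(acq, step_sd_mm = -1), "nonnegative")
})

test_that("the written dataset mirrors the expected layout", {
  net <- network_spec(n_roi = 6, n_communities = 2, seed = 2)
  acq <- acquisition_spec(grid_shape = c(10, 10, 10), scan_duration_s = 960,
                          analysis_onset_s = 160, n_blocks = 2,
                          block_duration_s = 160, bold_n_frames = 20)
  parc <- synthetic_parcellation(c(10, 10, 10), 6)
  subs <- lapply(1:2, function(i)
    simulate_subject(net, acq, parc, seed = i,
                     subject_id = sprintf("sub-%02d", i)))
  root <- withr::local_tempdir()
  write_synthetic_dataset(subs, root)
  expect_true(all(dir.exists(file.path(root, c("sub-01", "sub-02")))))
  ptab <- read.delim(file.path(root, "participants.tsv"))
  expect_equal(nrow(ptab), 2L)
  sidecar <- jsonlite::read_json(
    file.path(root, "sub-01", "pet", "sub-01_task-rest_pet.json"))
  expect_equal(sidecar$FrameDuration, 16)
  moco <- file.path(root, "derivatives", "mcflirt", "sub-01", "pet",
                    "sub-01_task-rest_pet_moco.par")
  expect_true(file.exists(moco))
  # .par writer/reader round-trips at the written precision
  back <- read_par(moco)
  expect_equal(unclass(back), round(unclass(subs[[1]]$motion), 6),
               ignore_attr = TRUE)
  # re-reading the written NIfTI reproduces the in-memory grid
  img <- read_nifti_image(
    file.path(root, "sub-01", "pet", "sub-01_task-rest_pet.nii.gz"),
    acq_frame_grid(acq))
  expect_equal(dim(img$data), dim(subs[[1]]$pet$data))
  expect_equal(img$data, subs[[1]]$pet$data, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(write_synthetic_dataset(list(), root), "at least one")
})
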