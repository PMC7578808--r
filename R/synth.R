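#' Acquisition specification for the synthetic generator
#'
#' Desk-scale emulation of the constant-infusion acquisition: a 5700-s scan
#' binned into 16-s frames, analysed over six 10-min blocks starting at
#' 30 min. The default synthetic grid is 40 x 40 x 40 voxels (the scanner
#' grid is far larger; the generator trades field of view for speed while
#' keeping the voxel size, point-spread and timing of the study).
#'
#' @param scan_duration_s scan duration (default 5700 s).
#' @param frame_duration_s PET frame duration (default 16 s).
#' @param analysis_onset_s analysis window onset (default 1800 s).
#' @param n_blocks number of analysis blocks (default 6).
#' @param block_duration_s block duration (default 600 s).
#' @param voxel_size_mm length-3 voxel size (default 2.09, 2.09, 2.03 mm).
#' @param grid_shape length-3 synthetic grid (default 40, 40, 40).
#' @param psf_fwhm_mm point-spread FWHM of the reconstruction post-filter
#'   (default 5 mm).
#' @param noise_sd white imaging-noise standard deviation, activity units
#'   (default 10).
#' @param bold_tr_s BOLD repetition time (default 2.45 s).
#' @param bold_n_frames BOLD volumes simulated (default 245, one 10-min
#'   run).
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(scan_duration_s = 5700, frame_duration_s = 16,
                             analysis_onset_s = 1800, n_blocks = 6,
                             block_duration_s = 600,
                             voxel_size_mm = c(2.09, 2.09, 2.03),
                             grid_shape = c(40, 40, 40),
                             psf_fwhm_mm = 5, noise_sd = 10,
                             bold_tr_s = 2.45, bold_n_frames = 245) {
  stopif_not_scalar(scan_duration_s, "scan_duration_s", positive = TRUE)
  stopif_not_scalar(frame_duration_s, "frame_duration_s", positive = TRUE)
  stopif_not_scalar(psf_fwhm_mm, "psf_fwhm_mm")
  stopif_not_scalar(noise_sd, "noise_sd")
  if (psf_fwhm_mm < 0 || noise_sd < 0)
    stop("psf_fwhm_mm and noise_sd must be nonnegative", call. = FALSE)
  if (analysis_onset_s + n_blocks * block_duration_s > scan_duration_s)
    stop("analysis window must fit inside the scan", call. = FALSE)
  structure(list(
    scan_duration_s = scan_duration_s, frame_duration_s = frame_duration_s,
    analysis_onset_s = analysis_onset_s, n_blocks = n_blocks,
    block_duration_s = block_duration_s,
    voxel_size_mm = as.numeric(voxel_size_mm),
    grid_shape = as.integer(grid_shape),
    psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
    bold_tr_s = bold_tr_s, bold_n_frames = as.integer(bold_n_frames)
  ), class = "acquisition_spec")
}

#' Frame grid of an acquisition specification
#' @param acq an [acquisition_spec()].
#' @return A [build_frame_grid()] object.
#' @export
acq_frame_grid <- function(acq) {
  build_frame_grid(acq$scan_duration_s, acq$frame_duration_s,
                   acq$analysis_onset_s)
}

#' Planted inter-regional network specification
#'
#' Defines the population correlation structure planted on the
#' instantaneous uptake signal: regions are partitioned into communities;
#' pairs within a community correlate at `rho_within`, pairs across
#' communities at `rho_between`. With `rho_within > rho_between >= 0` the
#' implied equal-block correlation matrix is positive semi-definite.
#'
#' @param n_roi number of regions (default 82).
#' @param n_communities number of communities used when
#'   `block_assignment` is not given (default 4, contiguous blocks).
#' @param block_assignment integer vector of community labels, one per
#'   ROI.
#' @param rho_within within-community correlation in `[0, 1)`
#'   (default 0.5).
#' @param rho_between between-community correlation in `[0, 1)`
#'   (default 0.1).
#' @param signal_sd standard deviation of the planted uptake-rate
#'   fluctuation, activity units per second (default 1).
#' @param seed default RNG seed used by the simulators.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_roi = 82, n_communities = 4,
                         block_assignment = NULL, rho_within = 0.5,
                         rho_between = 0.1, signal_sd = 1, seed = 1) {
  n_roi <- as.integer(n_roi)
  if (is.null(block_assignment))
    block_assignment <- sort(rep_len(seq_len(n_communities), n_roi))
  block_assignment <- as.integer(block_assignment)
  if (length(block_assignment) != n_roi)
    stop("block_assignment must have one label per ROI", call. = FALSE)
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0 ||
      rho_between >= 1)
    stop("correlations must lie in [0, 1)", call. = FALSE)
  stopif_not_scalar(signal_sd, "signal_sd", positive = TRUE)
  spec <- structure(list(
    n_roi = n_roi, block_assignment = block_assignment,
    rho_within = rho_within, rho_between = rho_between,
    signal_sd = signal_sd, seed = seed
  ), class = "network_spec")
  C <- network_correlation(spec)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("implied correlation matrix is not positive semi-definite",
         call. = FALSE)
  spec
}

#' Implied population correlation matrix of a network specification
#' @param net a [network_spec()].
#' @return An `n_roi` x `n_roi` correlation matrix.
#' @export
network_correlation <- function(net) {
  same <- outer(net$block_assignment, net$block_assignment, "==")
  C <- ifelse(same, net$rho_within, net$rho_between)
  diag(C) <- 1
  C
}

# symmetric matrix square root (eigen); tiny negative eigenvalues clipped
matrix_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("matrix is not positive semi-definite", call. = FALSE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Noiseless plasma input function
#'
#' Concave quadratic through the origin peaking at `peak_time_s`, the shape
#' of constant-infusion plasma radioactivity (rising throughout the scan to
#' a peak near 90 min).
#'
#' @param t_s times in seconds.
#' @param peak_time_s time of the peak (default 5400 s).
#' @param peak_value activity at the peak (default 100, arbitrary units).
#' @return Activity values at `t_s`.
#' @export
plasma_input <- function(t_s, peak_time_s = 5400, peak_value = 100) {
  peak_value * (2 * t_s * peak_time_s - t_s^2) / peak_time_s^2
}

#' Simulate constant-infusion blood samples
#'
#' Draws plasma samples on a regular schedule from the noiseless quadratic
#' input function, applies multiplicative measurement noise, and populates
#' the well-counter fields (raw counts over a counting duration, with
#' physical decay applied) so that decay correction can be exercised
#' downstream.
#'
#' @param acq an [acquisition_spec()].
#' @param peak_time_s plasma peak time (default 5400 s, i.e. 90 min).
#' @param peak_value peak activity (default 100).
#' @param noise_cv multiplicative measurement noise coefficient of
#'   variation (default 0.03; 0 for noiseless samples).
#' @param first_sample_s first draw time (default 600 s).
#' @param sample_interval_s draw spacing (default 600 s).
#' @param count_duration_s well-counter duration (default 240 s).
#' @param half_life_s isotope half-life (default 6586.2 s, fluorine-18).
#' @param seed RNG seed.
#' @return Data frame of samples with columns `draw_time_s`, `raw_counts`,
#'   `count_duration_s`, `plasma_volume_mL`, `activity` (the noiseless +
#'   noise decay-corrected concentration the counts encode).
#' @export
simulate_plasma_input <- function(acq = acquisition_spec(),
                                  peak_time_s = 5400, peak_value = 100,
                                  noise_cv = 0.03, first_sample_s = 600,
                                  sample_interval_s = 600,
                                  count_duration_s = 240,
                                  half_life_s = 6586.2, seed = 1) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (peak_time_s <= 0 || peak_time_s > acq$scan_duration_s)
    stop("peak_time_s must lie within the scan", call. = FALSE)
  if (peak_time_s < first_sample_s)
    stop("plasma peak precedes the first sample", call. = FALSE)
  t <- seq(first_sample_s, acq$scan_duration_s, by = sample_interval_s)
  base <- plasma_input(t, peak_time_s, peak_value)
  act <- with_seed(seed, base * (1 + noise_cv * stats::rnorm(length(t))))
  act <- pmax(act, 0)
  # encode as raw well-counter counts: physical decay between infusion
  # onset (reference time) and the count start
  raw <- act * count_duration_s * 2^(-t / half_life_s)
  data.frame(draw_time_s = t, raw_counts = raw,
             count_duration_s = count_duration_s, plasma_volume_mL = 1,
             activity = act)
}

#' Simulate instantaneous ROI uptake rates
#'
#' Generates the instantaneous glucose uptake-rate signal the gradient
#' filter is designed to recover: a slowly varying plasma-driven baseline
#' common to all regions, plus zero-mean Gaussian fluctuations with the
#' planted inter-regional correlation (realised through a symmetric matrix
#' square root), floored at zero.
#'
#' @param net a [network_spec()].
#' @param acq an [acquisition_spec()].
#' @param frames 0-based frame indices to simulate (default: the analysis
#'   window of `acq`).
#' @param baseline_rate constant uptake-rate baseline, activity units per
#'   second (default 10).
#' @param plasma_gain amplitude of the plasma-tracking baseline component
#'   (default 1): baseline(t) = `baseline_rate + plasma_gain * p(t)/p(peak)`.
#' @param peak_time_s plasma peak time (default 5400 s).
#' @param seed RNG seed (default `net$seed`).
#' @return A [roi_timeseries()] of nonnegative rates (activity/s).
#' @export
simulate_roi_uptake <- function(net, acq = acquisition_spec(), frames = NULL,
                                baseline_rate = 10, plasma_gain = 1,
                                peak_time_s = 5400, seed = net$seed) {
  stopifnot(inherits(net, "network_spec"), inherits(acq, "acquisition_spec"))
  grid <- acq_frame_grid(acq)
  if (is.null(frames))
    frames <- analysis_window(grid, acq$n_blocks, acq$block_duration_s)
  t_mid <- grid$frame_mid_s[frames + 1L]
  n_f <- length(t_mid)
  S <- matrix_sqrt(network_correlation(net))
  z <- with_seed(seed, matrix(stats::rnorm(net$n_roi * n_f), net$n_roi, n_f))
  baseline <- baseline_rate +
    plasma_gain * plasma_input(t_mid, peak_time_s, 1)
  rates <- sweep(net$signal_sd * (S %*% z), 2, baseline, "+")
  rates[rates < 0] <- 0
  roi_timeseries(rates, seq_len(net$n_roi), t_mid, grid$frame_duration_s,
                 units = "activity/s")
}

#' Integrate uptake rates into cumulative uptake
#'
#' The scanner measures cumulative trapped activity; this converts an
#' instantaneous rate series into its running time-integral (per-ROI
#' cumulative sum scaled by the frame duration). The output is monotone
#' nondecreasing in time for every ROI.
#'
#' @param rates a [roi_timeseries()] of nonnegative rates.
#' @return A [roi_timeseries()] of cumulative uptake (activity units).
#' @export
integrate_cumulative <- function(rates) {
  stopifnot(inherits(rates, "roi_timeseries"))
  if (any(rates$values < 0))
    stop("rates must be nonnegative", call. = FALSE)
  cum <- t(apply(rates$values * rates$frame_duration_s, 1, cumsum))
  if (nrow(rates$values) == 1L) cum <- matrix(cum, nrow = 1L)
  roi_timeseries(cum, rates$roi_ids, rates$frame_mid_s,
                 rates$frame_duration_s, units = "activity")
}

#' Render ROI time courses into a 4-D dynamic image
#'
#' Paints each voxel with its region's time-activity curve, applies a
#' Gaussian point-spread blur of `acq$psf_fwhm_mm`, and adds white
#' Gaussian imaging noise of `noise_sd`. Background voxels (label 0) carry
#' noise only (plus any blur spill near region boundaries).
#'
#' @param ts a [roi_timeseries()] (typically cumulative uptake).
#' @param parc a [parcellation()] whose labels cover `ts$roi_ids`.
#' @param acq an [acquisition_spec()]; its `grid_shape` must match the
#'   parcellation.
#' @param seed RNG seed for the noise.
#' @param noise_sd noise standard deviation (default `acq$noise_sd`).
#' @param grid frame grid for the result (default the PET grid of `acq`).
#' @return A [dynamic_image()].
#' @export
render_volumes <- function(ts, parc, acq = acquisition_spec(), seed = 1,
                           noise_sd = acq$noise_sd, grid = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(parc, "parcellation"))
  if (!all(dim(parc$labels) == acq$grid_shape))
    stop("parcellation shape does not match acquisition grid_shape",
         call. = FALSE)
  if (!all(ts$roi_ids %in% parc$roi_ids))
    stop("parcellation labels do not cover the ROI set", call. = FALSE)
  if (is.null(grid)) grid <- acq_frame_grid(acq)
  d <- c(dim(parc$labels), ncol(ts$values))
  labv <- as.integer(parc$labels)
  # lookup table: label id -> row of ts (0 stays 0-valued)
  lut <- rep(0L, max(parc$roi_ids) + 1L)
  lut[ts$roi_ids + 1L] <- seq_along(ts$roi_ids)
  rowidx <- lut[labv + 1L]
  vals <- rbind(0, ts$values)  # row 1 = background zeros
  x <- vals[rowidx + 1L, , drop = FALSE]
  dim(x) <- d
  sigma_vox <- (acq$psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / acq$voxel_size_mm
  if (acq$psf_fwhm_mm > 0) x <- gaussian_blur4d(x, sigma_vox)
  if (noise_sd > 0)
    x <- x + with_seed(seed, array(stats::rnorm(prod(d), sd = noise_sd), d))
  frame_indices <- as.integer(round(
    (ts$frame_mid_s - grid$frame_duration_s / 2) / grid$frame_duration_s))
  dynamic_image(x, grid, frame_indices = frame_indices,
                voxel_size_mm = acq$voxel_size_mm)
}

#' Simulate a rigid-motion trace
#'
#' Random-walk six-parameter motion (pitch, roll, yaw in radians; x, y, z
#' in mm), one row per frame, first frame at the origin.
#'
#' @param acq an [acquisition_spec()].
#' @param step_sd_mm per-frame translation step SD (default 0.25 mm).
#' @param step_sd_rad per-frame rotation step SD (default 0.002 rad).
#' @param seed RNG seed.
#' @param n_frames number of frames (default: the analysis window length,
#'   matching the realignment files of the study).
#' @return A `motion_trace`: numeric matrix with columns
#'   `pitch, roll, yaw, x, y, z`.
#' @export
simulate_motion <- function(acq = acquisition_spec(), step_sd_mm = 0.25,
                            step_sd_rad = 0.002, seed = 1, n_frames = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (step_sd_mm < 0 || step_sd_rad < 0)
    stop("step SDs must be nonnegative", call. = FALSE)
  if (is.null(n_frames))
    n_frames <- length(analysis_window(acq_frame_grid(acq), acq$n_blocks,
                                       acq$block_duration_s))
  steps <- with_seed(seed, cbind(
    matrix(stats::rnorm(3 * (n_frames - 1), sd = step_sd_rad),
           n_frames - 1, 3),
    matrix(stats::rnorm(3 * (n_frames - 1), sd = step_sd_mm),
           n_frames - 1, 3)))
  tr <- rbind(0, apply(steps, 2, cumsum))
  if (n_frames == 2L) tr <- rbind(0, matrix(steps, 1, 6))
  colnames(tr) <- c("pitch", "roll", "yaw", "x", "y", "z")
  structure(tr, class = c("motion_trace", "matrix"))
}

#' Simulate one synthetic subject
#'
#' Produces the full per-subject bundle the pipeline consumes: a dynamic
#' PET image over the whole scan (cumulative uptake rendered with blur and
#' noise), a short BOLD run with the same planted network plus slow drift,
#' blood samples, a motion trace, and a participants-table row.
#'
#' @param net a [network_spec()].
#' @param acq an [acquisition_spec()].
#' @param parc a [parcellation()] (default: synthetic tiling of
#'   `acq$grid_shape`).
#' @param seed master RNG seed for this subject.
#' @param subject_id subject label, e.g. `"sub-01"`.
#' @return List with elements `pet` ([dynamic_image()]), `bold`
#'   ([dynamic_image()]), `blood` (data frame), `motion`
#'   ([simulate_motion()]), `truth` (list of planted quantities) and
#'   `participant` (one-row data frame).
#' @export
simulate_subject <- function(net, acq = acquisition_spec(),
                             parc = synthetic_parcellation(acq$grid_shape,
                                                           net$n_roi),
                             seed = 1, subject_id = "sub-01") {
  grid <- acq_frame_grid(acq)
  all_frames <- seq_len(grid$n_frames) - 1L
  rates <- simulate_roi_uptake(net, acq, frames = all_frames,
                               seed = derive_seed(seed, 1))
  cum <- integrate_cumulative(rates)
  pet <- render_volumes(cum, parc, acq, seed = derive_seed(seed, 2))
  # BOLD: same planted network, slow drift to exercise the high-pass step
  bold_grid <- build_frame_grid(acq$bold_n_frames * acq$bold_tr_s,
                                acq$bold_tr_s, 0)
  nb <- bold_grid$n_frames
  S <- matrix_sqrt(network_correlation(net))
  bold_vals <- with_seed(derive_seed(seed, 3), {
    z <- S %*% matrix(stats::rnorm(net$n_roi * nb), net$n_roi, nb)
    drift <- stats::rnorm(net$n_roi, sd = 2) %o% seq(0, 1, length.out = nb)
    100 + 2 * z + drift
  })
  bold_ts <- roi_timeseries(bold_vals, seq_len(net$n_roi),
                            bold_grid$frame_mid_s, acq$bold_tr_s,
                            units = "BOLD")
  bold <- render_volumes(bold_ts, parc, acq, seed = derive_seed(seed, 4),
                         noise_sd = 2, grid = bold_grid)
  # blood schedule scales with the scan: ~10-min draws over a 95-min scan,
  # plasma peaking near the 90-min mark
  interval <- acq$scan_duration_s / 9.5
  blood <- simulate_plasma_input(acq,
                                 peak_time_s = min(5400,
                                                   0.95 * acq$scan_duration_s),
                                 first_sample_s = interval,
                                 sample_interval_s = interval,
                                 seed = derive_seed(seed, 5))
  # per-subject motion severity varies log-normally around a 0.25-mm
  # framewise step, giving realistic spread in the group QC summary
  motion_sd <- with_seed(derive_seed(seed, 8),
                         0.25 * exp(stats::rnorm(1, sd = 0.35)))
  motion <- simulate_motion(acq, step_sd_mm = motion_sd,
                            seed = derive_seed(seed, 6))
  participant <- with_seed(derive_seed(seed, 7), data.frame(
    participant_id = subject_id,
    age = sample(18:23, 1),
    sex = sample(c("M", "F"), 1),
    handedness = "R"))
  list(pet = pet, bold = bold, blood = blood, motion = motion,
       truth = list(rates = rates, cumulative = cum, network = net),
       participant = participant, subject_id = subject_id, parc = parc,
       acq = acq)
}

# write one subject's files under a dataset root (BIDS-like layout)
write_subject <- function(subj, root) {
  sid <- subj$subject_id
  pet_dir <- file.path(root, sid, "pet")
  func_dir <- file.path(root, sid, "func")
  moco_dir <- file.path(root, "derivatives", "mcflirt", sid, "pet")
  for (dd in c(pet_dir, func_dir, moco_dir))
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  acq <- subj$acq
  write_nifti_image(subj$pet, file.path(pet_dir,
                                        paste0(sid, "_task-rest_pet.nii.gz")))
  jsonlite::write_json(list(
    Modality = "PT", TracerName = "FDG", InfusionMode = "constant",
    FrameDuration = acq$frame_duration_s,
    FrameTimesStart = subj$pet$grid$frame_start_s,
    VoxelSize = acq$voxel_size_mm, Units = "arbitrary"),
    file.path(pet_dir, paste0(sid, "_task-rest_pet.json")),
    auto_unbox = TRUE, digits = NA)
  write_nifti_image(subj$bold, file.path(func_dir,
                                         paste0(sid, "_task-rest_bold.nii.gz")))
  jsonlite::write_json(list(
    Modality = "MR", RepetitionTime = acq$bold_tr_s, TaskName = "rest"),
    file.path(func_dir, paste0(sid, "_task-rest_bold.json")),
    auto_unbox = TRUE, digits = NA)
  write_blood_samples(subj$blood,
                      file.path(pet_dir, paste0(sid, "_task-rest_blood.tsv")))
  write_par(subj$motion,
            file.path(moco_dir, paste0(sid, "_task-rest_pet_moco.par")))
  invisible(sid)
}

#' Write a synthetic dataset to disk
#'
#' Emits the BIDS-like layout of the study: `sub-*/pet/*_pet.nii.gz` with
#' JSON sidecar, `sub-*/func/*_bold.nii.gz`, blood-sample TSVs,
#' `derivatives/mcflirt/sub-*/pet/*_moco.par` realignment files, a shared
#' synthetic parcellation under `derivatives/parcellation/`, and
#' `participants.tsv`.
#'
#' @param subjects list of [simulate_subject()] bundles.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(subjects, out_dir) {
  if (length(subjects) < 1L)
    stop("need at least one subject", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  for (s in subjects) write_subject(s, out_dir)
  parc <- subjects[[1]]$parc
  parc_dir <- file.path(out_dir, "derivatives", "parcellation")
  dir.create(parc_dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(parc$labels,
                     file.path(parc_dir, "atlas-synthetic_dseg.nii.gz"))
  ptab <- do.call(rbind, lapply(subjects, `[[`, "participant"))
  utils::write.table(ptab, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(Name = "fpetconn synthetic dataset",
                            BIDSVersion = "1.4.0",
                            GeneratedBy = list(Name = "fpetconn")),
                       file.path(out_dir, "dataset_description.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Simulate and write a multi-subject dataset, one subject at a time
#'
#' Convenience wrapper around [simulate_subject()] and
#' [write_synthetic_dataset()] that keeps at most one subject in memory.
#'
#' @param n_subjects number of subjects.
#' @param out_dir output directory.
#' @param net,acq network and acquisition specifications.
#' @param seed master seed; subject `i` uses a seed derived from it.
#' @return `out_dir`, invisibly.
#' @export
simulate_dataset <- function(n_subjects, out_dir, net = network_spec(),
                             acq = acquisition_spec(), seed = 1) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  parc <- synthetic_parcellation(acq$grid_shape, net$n_roi)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub-%02d", i)
    s <- simulate_subject(net, acq, parc, seed = derive_seed(seed, 100 * i),
                          subject_id = sid)
    write_subject(s, out_dir)
    rows[[i]] <- s$participant
  }
  parc_dir <- file.path(out_dir, "derivatives", "parcellation")
  dir.create(parc_dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(parc$labels,
                     file.path(parc_dir, "atlas-synthetic_dseg.nii.gz"))
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(Name = "fpetconn synthetic dataset",
                            BIDSVersion = "1.4.0",
                            GeneratedBy = list(Name = "fpetconn")),
                       file.path(out_dir, "dataset_description.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
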