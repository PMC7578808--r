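#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one serialisable
#' object: acquisition timing and geometry, gradient-filter widths and edge
#' policy, connectivity aggregation options, plasma constants, synthetic
#' generator settings and the master seed. The object round-trips through
#' a plain-text YAML file ([write_config()] / [read_config()]).
#'
#' @param acquisition named list of [acquisition_spec()] arguments.
#' @param filter named list: `sigma_s` (voxels), `sigma_t` (frames),
#'   `window`, `edge_policy`.
#' @param connectivity named list: `fisher` (Fisher-z group averaging),
#'   `n_blocks`, `block_duration_s`.
#' @param plasma named list: `half_life_s`, `fit_decay_corrected`.
#' @param network named list of [network_spec()] arguments (used by the
#'   synthetic generator).
#' @param seed master seed.
#' @param strict abort the group run on the first failing subject
#'   (default `FALSE`: failing subjects are skipped with a warning).
#' @return A `pipeline_config` object (a named list).
#' @export
pipeline_config <- function(acquisition = list(), filter = list(),
                            connectivity = list(), plasma = list(),
                            network = list(), seed = 1, strict = FALSE) {
  cfg <- list(
    acquisition = utils::modifyList(list(
      scan_duration_s = 5700, frame_duration_s = 16, analysis_onset_s = 1800,
      n_blocks = 6, block_duration_s = 600,
      voxel_size_mm = c(2.09, 2.09, 2.03), grid_shape = c(40, 40, 40),
      psf_fwhm_mm = 5, noise_sd = 10, bold_tr_s = 2.45,
      bold_n_frames = 245), acquisition),
    filter = utils::modifyList(list(
      sigma_s = 1, sigma_t = 2, window = 7, edge_policy = "valid"), filter),
    connectivity = utils::modifyList(list(
      fisher = TRUE, n_blocks = 6, block_duration_s = 600), connectivity),
    plasma = utils::modifyList(list(
      half_life_s = 6586.2, fit_decay_corrected = TRUE), plasma),
    network = utils::modifyList(list(
      n_roi = 82, n_communities = 4, rho_within = 0.5, rho_between = 0.1,
      signal_sd = 1), network),
    seed = seed, strict = strict)
  with(cfg$filter, {
    if (!(edge_policy %in% c("valid", "renormalized")))
      stop("edge_policy must be 'valid' or 'renormalized'", call. = FALSE)
    if (sigma_s <= 0 || sigma_t <= 0 || window < 3 || window %% 2 != 1)
      stop("invalid filter parameters", call. = FALSE)
  })
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

acq_from_config <- function(config) do.call(acquisition_spec,
                                            config$acquisition)

#' Discover a BIDS-like fPET/fMRI dataset layout
#'
#' Enumerates `sub-*` folders and locates, per subject, the dynamic PET
#' image, the BOLD image, the blood-sample table and the realignment
#' `.par` derivative, plus the shared parcellation volume and
#' `participants.tsv`. Missing optional files are recorded as `NA` and
#' logged; a dataset with no subjects is an error.
#'
#' @param root dataset root directory.
#' @return A `dataset_layout` object: list with `root`, `subjects` (data
#'   frame of per-subject paths), `parcellation`, `participants`.
#' @export
discover_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  subs <- sort(basename(Filter(dir.exists,
                               list.files(root, pattern = "^sub-",
                                          full.names = TRUE))))
  if (length(subs) == 0L)
    stop("no sub-* folders found under ", root, call. = FALSE)
  find1 <- function(dir, pattern) {
    f <- list.files(dir, pattern = pattern, full.names = TRUE)
    if (length(f) >= 1L) f[1] else NA_character_
  }
  rows <- lapply(subs, function(s) {
    pet <- find1(file.path(root, s, "pet"), "_pet\\.nii(\\.gz)?$")
    func <- find1(file.path(root, s, "func"), "_bold\\.nii(\\.gz)?$")
    blood <- find1(file.path(root, s, "pet"), "_blood\\.tsv$")
    par <- find1(file.path(root, "derivatives", "mcflirt", s, "pet"),
                 "\\.par$")
    if (is.na(func))
      message("subject ", s, ": no BOLD image found (PET-only)")
    data.frame(subject = s, pet = pet, func = func, blood = blood,
               par = par, stringsAsFactors = FALSE)
  })
  parc <- find1(file.path(root, "derivatives", "parcellation"),
                "\\.nii(\\.gz)?$")
  participants <- file.path(root, "participants.tsv")
  structure(list(root = root, subjects = do.call(rbind, rows),
                 parcellation = parc,
                 participants = if (file.exists(participants))
                   participants else NA_character_),
            class = "dataset_layout")
}

#' @export
print.dataset_layout <- function(x, ...) {
  cat(sprintf("<dataset_layout> %s: %d subject(s)\n", x$root,
              nrow(x$subjects)))
  invisible(x)
}

#' Run the full connectivity pipeline on a dataset
#'
#' Executes, per subject, the fPET path (analysis-window selection ->
#' spatio-temporal gradient filter -> parcellation -> Pearson
#' connectivity), the static path (frame sum -> regional means, pooled
#' across subjects into a demeaned metabolic-covariance matrix), the fMRI
#' path (parcellation -> high-pass -> connectivity), plasma-curve fitting
#' on decay-corrected blood samples, and motion QC; then group-averages
#' the subject matrices on the Fisher-z scale. All products are written
#' under `derivatives/fpetconn/` together with a provenance JSON that
#' records every parameter and seed.
#'
#' @param config a [pipeline_config()].
#' @param layout a [discover_dataset()] layout.
#' @param out_dir output directory (default
#'   `file.path(layout$root, "derivatives", "fpetconn")`).
#' @return A result bundle: list with `subject_fpet`, `subject_fmri`
#'   (lists of [connectivity_matrix()]), `group_fpet`, `group_fmri`,
#'   `static_covariance`, `plasma_fits`, `motion`, `failed`, `out_dir`.
#' @export
run_pipeline <- function(config, layout,
                         out_dir = file.path(layout$root, "derivatives",
                                             "fpetconn")) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(layout, "dataset_layout"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- acq_from_config(config)
  grid <- acq_frame_grid(acq)
  window <- analysis_window(grid, config$connectivity$n_blocks,
                            config$connectivity$block_duration_s)
  kernel <- build_gradient_kernel(config$filter$sigma_s,
                                  config$filter$sigma_t,
                                  config$filter$window)
  if (is.na(layout$parcellation))
    stop("layout has no parcellation volume", call. = FALSE)
  parc <- read_parcellation(layout$parcellation)
  bold_grid <- build_frame_grid(acq$bold_n_frames * acq$bold_tr_s,
                                acq$bold_tr_s, 0)

  subject_fpet <- list(); subject_fmri <- list()
  static_rows <- list(); plasma_fits <- list(); motions <- list()
  failed <- character(0)

  for (i in seq_len(nrow(layout$subjects))) {
    row <- layout$subjects[i, ]
    sid <- row$subject
    res <- tryCatch({
      pet <- read_nifti_image(row$pet, grid)
      pet_win <- subset_frames(pet, window)
      grad <- apply_gradient_filter(pet_win, kernel,
                                    config$filter$edge_policy)
      ts <- extract_roi_timeseries(grad, parc)
      fpet_mat <- subject_connectivity(ts, modality = "fpet")
      write_connectivity(fpet_mat,
                         file.path(out_dir,
                                   paste0(sid, "_fpet_connectivity.tsv")),
                         provenance = list(subject = sid,
                                           sigma_s = config$filter$sigma_s,
                                           sigma_t = config$filter$sigma_t,
                                           edge_policy = config$filter$edge_policy,
                                           frame_window = range(window)))
      st <- static_image(pet_win)
      st_ts <- extract_roi_timeseries(
        dynamic_image(st, grid, frame_indices = window[1],
                      voxel_size_mm = pet$voxel_size_mm), parc)
      fmri_mat <- NULL
      if (!is.na(row$func)) {
        bold <- read_nifti_image(row$func, bold_grid)
        bts <- highpass_fmri(extract_roi_timeseries(bold, parc),
                             tr_s = acq$bold_tr_s)
        fmri_mat <- subject_connectivity(bts, modality = "fmri")
        write_connectivity(fmri_mat,
                           file.path(out_dir,
                                     paste0(sid, "_fmri_connectivity.tsv")),
                           provenance = list(subject = sid,
                                             highpass_hz = 0.01))
      }
      fit <- NULL
      if (!is.na(row$blood)) {
        blood <- read_blood_samples(row$blood)
        blood$activity <- decay_correct(blood$raw_counts,
                                        blood$count_duration_s,
                                        blood$draw_time_s,
                                        config$plasma$half_life_s)
        fit <- fit_plasma_curve(blood)
      }
      mot <- if (!is.na(row$par)) read_par(row$par) else NULL
      list(fpet = fpet_mat, fmri = fmri_mat, static = st_ts$values[, 1],
           fit = fit, motion = mot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (isTRUE(config$strict))
        stop("subject ", sid, " failed: ", conditionMessage(res),
             call. = FALSE)
      warning("skipping subject ", sid, ": ", conditionMessage(res),
              call. = FALSE)
      failed <- c(failed, sid)
      next
    }
    subject_fpet[[sid]] <- res$fpet
    if (!is.null(res$fmri)) subject_fmri[[sid]] <- res$fmri
    static_rows[[sid]] <- res$static
    if (!is.null(res$fit)) plasma_fits[[sid]] <- res$fit
    if (!is.null(res$motion)) motions[[sid]] <- res$motion
  }
  if (length(subject_fpet) == 0L)
    stop("no subject completed the fPET path", call. = FALSE)

  group_fpet <- group_average(subject_fpet,
                              fisher = config$connectivity$fisher)
  write_connectivity(group_fpet,
                     file.path(out_dir, "group_fpet_connectivity.tsv"),
                     provenance = list(n_subjects = length(subject_fpet),
                                       fisher = config$connectivity$fisher))
  group_fmri <- NULL
  if (length(subject_fmri) > 0L) {
    group_fmri <- group_average(subject_fmri,
                                fisher = config$connectivity$fisher)
    write_connectivity(group_fmri,
                       file.path(out_dir, "group_fmri_connectivity.tsv"),
                       provenance = list(n_subjects = length(subject_fmri)))
  }
  static_cov <- NULL
  if (length(static_rows) >= 3L) {
    smat <- do.call(rbind, static_rows)
    static_cov <- metabolic_covariance(smat,
                                       roi_ids = subject_fpet[[1]]$roi_ids)
    write_connectivity(static_cov,
                       file.path(out_dir, "group_static_covariance.tsv"),
                       provenance = list(n_subjects = length(static_rows)))
  }
  motion_summary <- NULL
  if (length(motions) > 0L) {
    motion_summary <- group_motion_summary(motions)
    utils::write.table(
      data.frame(subject = names(motion_summary$per_subject),
                 mean_relative_displacement_mm = motion_summary$per_subject),
      file.path(out_dir, "qc_motion.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (length(plasma_fits) > 0L) {
    ptab <- data.frame(subject = names(plasma_fits),
                       c0 = vapply(plasma_fits, `[[`, 0, "c0"),
                       c1 = vapply(plasma_fits, `[[`, 0, "c1"),
                       c2 = vapply(plasma_fits, `[[`, 0, "c2"))
    utils::write.table(ptab, file.path(out_dir, "plasma_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(package = "fpetconn", config = unclass(config),
         n_subjects = nrow(layout$subjects), failed = failed,
         frame_window = range(window),
         plasma_fit_on = if (config$plasma$fit_decay_corrected)
           "decay_corrected" else "raw"),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(subject_fpet = subject_fpet, subject_fmri = subject_fmri,
                 group_fpet = group_fpet, group_fmri = group_fmri,
                 static_covariance = static_cov,
                 plasma_fits = plasma_fits, motion = motion_summary,
                 failed = failed, out_dir = out_dir))
}
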