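#' Frame grid for a constant-infusion dynamic PET acquisition
#'
#' List-mode PET data are binned post hoc into contiguous frames of fixed
#' duration. `build_frame_grid()` computes the frame timing for such an
#' acquisition: with the study defaults (5700 s scan, 16 s frames) it yields
#' 356 complete frames; a partial trailing frame is discarded. Frames are
#' indexed 0-based and cover half-open intervals
#' `[i * frame_duration_s, (i + 1) * frame_duration_s)`.
#'
#' @param scan_duration_s total acquisition duration in seconds (> 0).
#' @param frame_duration_s frame (bin) duration in seconds (> 0, <= scan).
#' @param analysis_onset_s start of the analysis window in seconds from
#'   infusion onset (>= 0, < scan duration). Infusion onset coincides with
#'   the PET start, so all times share one origin.
#' @return A `frame_grid` object: a list with `scan_duration_s`,
#'   `frame_duration_s`, `analysis_onset_s`, `n_frames`, and per-frame
#'   `frame_start_s` / `frame_mid_s` vectors.
#' @examples
#' g <- build_frame_grid(5700, 16, 1800)
#' g$n_frames  # 356
#' @export
build_frame_grid <- function(scan_duration_s = 5700, frame_duration_s = 16,
                             analysis_onset_s = 1800) {
  stopif_not_scalar(scan_duration_s, "scan_duration_s", positive = TRUE)
  stopif_not_scalar(frame_duration_s, "frame_duration_s", positive = TRUE)
  stopif_not_scalar(analysis_onset_s, "analysis_onset_s")
  if (frame_duration_s > scan_duration_s)
    stop("frame_duration_s exceeds scan_duration_s", call. = FALSE)
  if (analysis_onset_s < 0 || analysis_onset_s >= scan_duration_s)
    stop("analysis_onset_s must lie within [0, scan_duration_s)", call. = FALSE)
  n <- floor(scan_duration_s / frame_duration_s)
  start <- (seq_len(n) - 1) * frame_duration_s
  structure(list(
    scan_duration_s = scan_duration_s,
    frame_duration_s = frame_duration_s,
    analysis_onset_s = analysis_onset_s,
    n_frames = as.integer(n),
    frame_start_s = start,
    frame_mid_s = start + frame_duration_s / 2
  ), class = "frame_grid")
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf("<frame_grid> %d frames of %g s over %g s (analysis onset %g s)\n",
              x$n_frames, x$frame_duration_s, x$scan_duration_s,
              x$analysis_onset_s))
  invisible(x)
}

#' Frame indices of the analysis window
#'
#' Returns the 0-based indices of the frames retained for analysis: the
#' window starts at the frame containing `analysis_onset_s`
#' (index `floor(onset / frame_duration)`) and spans
#' `floor(n_blocks * block_duration_s / frame_duration_s)` consecutive
#' frames. With the study defaults (onset 30 min, six 10-min blocks of 16-s
#' frames) this selects exactly 225 frames starting at index 112.
#'
#' @param grid a [build_frame_grid()] object.
#' @param n_blocks number of analysis blocks (default 6).
#' @param block_duration_s block duration in seconds (default 600).
#' @return Integer vector of 0-based frame indices.
#' @export
analysis_window <- function(grid, n_blocks = 6, block_duration_s = 600) {
  stopifnot(inherits(grid, "frame_grid"))
  stopif_not_scalar(n_blocks, "n_blocks", positive = TRUE)
  stopif_not_scalar(block_duration_s, "block_duration_s", positive = TRUE)
  window_s <- n_blocks * block_duration_s
  if (grid$analysis_onset_s + window_s > grid$scan_duration_s)
    stop("analysis window extends beyond the scan", call. = FALSE)
  first <- floor(grid$analysis_onset_s / grid$frame_duration_s)
  n <- floor(window_s / grid$frame_duration_s)
  if (first + n > grid$n_frames)
    stop("analysis window extends beyond the binned frames", call. = FALSE)
  as.integer(seq.int(first, length.out = n))
}

#' Decay-correct well-counter measurements
#'
#' Converts raw counts accumulated over `count_duration_s` into a count rate
#' and references it back to a common reference time (infusion onset) by
#' multiplying with `2^(elapsed_s / half_life_s)`. The default half-life is
#' that of fluorine-18, 109.77 min.
#'
#' @param raw_counts total counts recorded (> 0).
#' @param count_duration_s counting duration in seconds (> 0).
#' @param elapsed_s time elapsed between the reference time and the count
#'   start (>= 0).
#' @param half_life_s isotope half-life in seconds (> 0; default 6586.2,
#'   fluorine-18).
#' @return Decay-corrected count rate (counts per second, arbitrary
#'   activity scale). Vectorised over its arguments.
#' @examples
#' decay_correct(1000, 240, 6586.2)  # one half-life: factor exactly 2
#' @export
decay_correct <- function(raw_counts, count_duration_s, elapsed_s,
                          half_life_s = 6586.2) {
  if (any(!is.finite(raw_counts)) || any(raw_counts < 0))
    stop("raw_counts must be finite and nonnegative", call. = FALSE)
  if (any(count_duration_s <= 0))
    stop("count_duration_s must be positive", call. = FALSE)
  if (any(elapsed_s < 0))
    stop("elapsed_s must be nonnegative", call. = FALSE)
  if (any(half_life_s <= 0))
    stop("half_life_s must be positive", call. = FALSE)
  (raw_counts / count_duration_s) * 2^(elapsed_s / half_life_s)
}

#' Fit a quadratic plasma radioactivity curve
#'
#' Fits, by least squares, a second-order polynomial
#' `activity(t) = c0 + c1 t + c2 t^2` to decay-corrected plasma samples,
#' as done per subject for constant-infusion blood data.
#'
#' @param samples a data frame of plasma samples with columns `draw_time_s`
#'   and `activity` (e.g. from [simulate_plasma_input()] after decay
#'   correction, or [read_blood_samples()] + [decay_correct()]).
#' @return A `plasma_curve` object: list with `c0`, `c1`, `c2`,
#'   `fit_window_s` (range of sample times) and `n_samples_used`.
#' @export
fit_plasma_curve <- function(samples) {
  samples <- as.data.frame(samples)
  if (!all(c("draw_time_s", "activity") %in% names(samples)))
    stop("samples must have columns draw_time_s and activity", call. = FALSE)
  t <- samples$draw_time_s
  y <- samples$activity
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(unique(t)) < 3L)
    stop("plasma fit requires >= 3 samples with distinct draw times",
         call. = FALSE)
  X <- cbind(1, t, t^2)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("collinear design: sample times do not identify a quadratic",
         call. = FALSE)
  beta <- qr.coef(qx, y)
  structure(list(
    c0 = unname(beta[1]), c1 = unname(beta[2]), c2 = unname(beta[3]),
    fit_window_s = range(t), n_samples_used = length(t)
  ), class = "plasma_curve")
}

#' Evaluate a fitted plasma curve
#'
#' @param curve a [fit_plasma_curve()] object.
#' @param t_s numeric vector of times (seconds).
#' @return Fitted activity at `t_s`.
#' @export
predict_plasma_curve <- function(curve, t_s) {
  stopifnot(inherits(curve, "plasma_curve"))
  curve$c0 + curve$c1 * t_s + curve$c2 * t_s^2
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> activity(t) = %.4g + %.4g t + %.4g t^2 (n = %d)\n",
              x$c0, x$c1, x$c2, x$n_samples_used))
  invisible(x)
}

#' Group-average plasma curve
#'
#' Evaluates each subject's fitted quadratic on a common time grid and
#' returns the pointwise mean, mirroring the group curve overlaid on the
#' individual plasma fits.
#'
#' @param curves list of [fit_plasma_curve()] objects.
#' @param grid_s numeric vector of evaluation times (seconds).
#' @return Data frame with columns `t_s` and `activity` (the group mean).
#' @export
group_average_curve <- function(curves, grid_s) {
  if (length(curves) == 0L)
    stop("need at least one plasma curve", call. = FALSE)
  vals <- vapply(curves, predict_plasma_curve, numeric(length(grid_s)),
                 t_s = grid_s)
  vals <- matrix(vals, nrow = length(grid_s))
  data.frame(t_s = grid_s, activity = rowMeans(vals))
}

#' Read / write blood-sample tables
#'
#' Blood samples are stored as tab-separated text with columns
#' `draw_time_s`, `raw_counts`, `count_duration_s`, `plasma_volume_mL`
#' (plus `activity` when already decay-corrected).
#'
#' @param path file path.
#' @return `read_blood_samples()`: a data frame of samples.
#' @export
read_blood_samples <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("draw_time_s", "raw_counts", "count_duration_s", "plasma_volume_mL")
  if (!all(need %in% names(df)))
    stop("blood-sample table lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_blood_samples
#' @param samples data frame of samples.
#' @export
write_blood_samples <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
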