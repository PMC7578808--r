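#' Read a 6-column realignment-parameter (".par") file
#'
#' Parses whitespace-delimited rigid-body realignment parameters, one frame
#' per line, column order pitch, roll, yaw (radians), x, y, z (mm) — the
#' dialect written by MCFLIRT and stored under `derivatives/mcflirt/` in
#' the dataset.
#'
#' @param path file path.
#' @return A `motion_trace` matrix (frames x 6).
#' @export
read_par <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 6L || anyNA(v))
      stop(sprintf("line %d of %s: expected 6 numeric columns, got %d",
                   i, path, length(f)), call. = FALSE)
    v
  })
  tr <- do.call(rbind, rows)
  colnames(tr) <- c("pitch", "roll", "yaw", "x", "y", "z")
  structure(tr, class = c("motion_trace", "matrix"))
}

#' Write a motion trace as a ".par" file
#'
#' @param trace a motion-trace matrix (frames x 6, columns pitch, roll,
#'   yaw, x, y, z).
#' @param path output path.
#' @param digits decimal digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_par <- function(trace, path, digits = 6) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L) stop("trace must have 6 columns", call. = FALSE)
  fmt <- paste(rep(sprintf("%%.%df", digits), 6), collapse = " ")
  writeLines(apply(trace, 1, function(r) do.call(sprintf, c(fmt, as.list(r)))),
             path)
  invisible(path)
}

#' Mean relative (framewise) translational displacement
#'
#' Summarises subject motion as the mean over frames of the Euclidean norm
#' of the frame-to-frame difference of the translation vector (x, y, z),
#' in mm. Rotations are carried in the trace but excluded from this
#' statistic.
#'
#' @param trace a motion-trace matrix (frames x 6).
#' @param per_axis if `TRUE`, also return the mean absolute framewise
#'   displacement separately for x, y and z.
#' @return The mean relative displacement in mm, or (with
#'   `per_axis = TRUE`) a list with `euclidean_mm` and `per_axis_mm`.
#' @export
mean_relative_displacement <- function(trace, per_axis = FALSE) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2L)
    stop("need at least 2 frames", call. = FALSE)
  d <- diff(trace[, 4:6, drop = FALSE])
  eu <- mean(sqrt(rowSums(d^2)))
  if (!per_axis) return(eu)
  list(euclidean_mm = eu,
       per_axis_mm = colMeans(abs(d)))
}

#' Group motion summary
#'
#' Per-subject mean relative translational displacement plus the
#' across-subject mean and maximum — the summary statistics reported for
#' the PET realignment parameters.
#'
#' @param traces list of motion-trace matrices (optionally named by
#'   subject).
#' @return List with `per_subject` (named numeric vector, mm), `mean_mm`
#'   and `max_mm`.
#' @export
group_motion_summary <- function(traces) {
  if (length(traces) == 0L)
    stop("need at least one motion trace", call. = FALSE)
  per <- vapply(traces, mean_relative_displacement, numeric(1))
  list(per_subject = per, mean_mm = mean(per), max_mm = max(per))
}
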