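#' Dynamic image container
#'
#' A `dynamic_image` bundles a 4-D intensity array (x, y, z, frame) with its
#' frame timing and voxel geometry. It is the central object of both the
#' fPET path (cumulative uptake, filtered uptake change) and the fMRI path.
#'
#' @param data 4-D numeric array (x, y, z, t); a 3-D array is promoted to a
#'   single frame.
#' @param grid a [build_frame_grid()] object describing the acquisition the
#'   frames were cut from.
#' @param frame_indices 0-based indices into `grid` for each frame of
#'   `data` (default: the first `dim(data)[4]` frames).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param spatial_offset length-3 integer: number of voxels trimmed from
#'   each low face relative to the acquisition grid (nonzero after
#'   "valid"-mode filtering); used to crop a parcellation to match.
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, grid, frame_indices = NULL,
                          voxel_size_mm = c(2.09, 2.09, 2.03),
                          spatial_offset = c(0L, 0L, 0L)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("data must be a 3-D or 4-D array", call. = FALSE)
  stopifnot(inherits(grid, "frame_grid"))
  if (is.null(frame_indices)) frame_indices <- seq_len(dim(data)[4]) - 1L
  if (length(frame_indices) != dim(data)[4])
    stop("frame_indices length must equal the number of frames", call. = FALSE)
  if (any(frame_indices < 0) || any(frame_indices >= grid$n_frames))
    stop("frame_indices out of range for the frame grid", call. = FALSE)
  structure(list(
    data = data,
    grid = grid,
    frame_indices = as.integer(frame_indices),
    voxel_size_mm = voxel_size_mm,
    spatial_offset = as.integer(spatial_offset)
  ), class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames (grid indices %d..%d)\n",
              d[1], d[2], d[3], d[4],
              min(x$frame_indices), max(x$frame_indices)))
  invisible(x)
}

#' Subset the frames of a dynamic image
#'
#' @param img a [dynamic_image()].
#' @param frame_indices 0-based frame-grid indices to retain (must be a
#'   subset of `img$frame_indices`), e.g. from [analysis_window()].
#' @return A `dynamic_image` restricted to those frames.
#' @export
subset_frames <- function(img, frame_indices) {
  stopifnot(inherits(img, "dynamic_image"))
  pos <- match(as.integer(frame_indices), img$frame_indices)
  if (anyNA(pos))
    stop("requested frames are not present in the image", call. = FALSE)
  dynamic_image(img$data[, , , pos, drop = FALSE], img$grid,
                frame_indices = img$frame_indices[pos],
                voxel_size_mm = img$voxel_size_mm,
                spatial_offset = img$spatial_offset)
}

#' Mid-frame times (seconds) of a dynamic image
#' @param img a [dynamic_image()].
#' @return Numeric vector of frame midpoints in seconds.
#' @export
frame_times <- function(img) {
  img$grid$frame_mid_s[img$frame_indices + 1L]
}

# ---- separable 1-D correlation machinery -----------------------------------

# operator matrix for correlating 1-D weights (offsets `off`) along an axis
# of length n. mode "valid": rows only where the full window fits.
# mode "same": one row per position, truncated at the edges and renormalised
# by `renorm` ("sum" -> unit sum, "ramp" -> unit response to u(t) = t).
corr_operator <- function(weights, off, n, mode = c("valid", "same"),
                          renorm = c("none", "sum", "ramp")) {
  mode <- match.arg(mode)
  renorm <- match.arg(renorm)
  w <- length(off)
  if (mode == "valid") {
    if (n < w) stop("axis shorter than the kernel window", call. = FALSE)
    n_out <- n - w + 1L
    A <- matrix(0, n_out, n)
    for (i in seq_len(n_out)) A[i, i:(i + w - 1L)] <- weights
    return(A)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off                # 1-based source positions
    ok <- j >= 1L & j <= n
    wi <- weights[ok]
    if (renorm == "sum") {
      s <- sum(wi)
      if (s != 0) wi <- wi / s
    } else if (renorm == "ramp") {
      # keep the truncated profile derivative-like: zero response to
      # constants (recenter), unit response to a unit-slope ramp (rescale)
      wi <- wi - sum(wi) / length(wi)
      s <- sum(wi * off[ok])
      if (s != 0) wi <- wi / s
    }
    A[i, j[ok]] <- wi
  }
  A
}

# apply operator matrix A (n_out x n_axis) along `axis` of 4-D array x
apply_along_axis <- function(x, axis, A) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  y <- aperm(x, perm)
  dy <- dim(y)
  dim(y) <- c(dy[1], prod(dy[-1]))
  y <- A %*% y
  dim(y) <- c(nrow(A), dy[-1])
  aperm(y, order(perm))
}

#' Apply the spatio-temporal gradient filter to a dynamic image
#'
#' Correlates the 4-D kernel with the image (the kernel is not flipped:
#' positive temporal offsets address later frames, so rising uptake yields
#' positive output). The kernel is separable, so the filter is applied as
#' four successive 1-D correlations; the result equals the full 4-D sliding
#' correlation.
#'
#' Under the default `"valid"` edge policy the output loses
#' `(window_extent - 1) / 2` voxels at each spatial face and the same
#' number of frames at each temporal end; `frame_indices` and
#' `spatial_offset` of the result are adjusted accordingly so downstream
#' parcellation stays aligned. Under `"renormalized"` the output keeps the
#' input geometry: near edges the truncated spatial lobe is rescaled to
#' unit sum and the truncated temporal profile to unit ramp response.
#'
#' @param img a [dynamic_image()] holding cumulative uptake.
#' @param kernel a [build_gradient_kernel()] object.
#' @param edge_policy `"valid"` (default) or `"renormalized"`.
#' @return A `dynamic_image` of uptake change per frame.
#' @export
apply_gradient_filter <- function(img, kernel = build_gradient_kernel(),
                                  edge_policy = c("valid", "renormalized")) {
  stopifnot(inherits(img, "dynamic_image"), inherits(kernel, "gradient_kernel"))
  edge_policy <- match.arg(edge_policy)
  d <- dim(img$data)
  w <- kernel$window_extent
  if (d[4] < w)
    stop(sprintf("image has %d frames; kernel window needs >= %d", d[4], w),
         call. = FALSE)
  if (any(d[1:3] < w) && edge_policy == "valid")
    stop("spatial extent smaller than the kernel window", call. = FALSE)
  half <- (w - 1L) %/% 2L
  x <- img$data
  if (edge_policy == "valid") {
    for (ax in 1:3)
      x <- apply_along_axis(x, ax, corr_operator(kernel$spatial_1d,
                                                 kernel$offsets, d[ax], "valid"))
    x <- apply_along_axis(x, 4L, corr_operator(kernel$temporal_1d,
                                               kernel$offsets, d[4], "valid"))
    keep <- seq.int(half + 1L, d[4] - half)
    dynamic_image(x, img$grid,
                  frame_indices = img$frame_indices[keep],
                  voxel_size_mm = img$voxel_size_mm,
                  spatial_offset = img$spatial_offset + half)
  } else {
    for (ax in 1:3)
      x <- apply_along_axis(x, ax, corr_operator(kernel$spatial_1d,
                                                 kernel$offsets, d[ax], "same",
                                                 renorm = "sum"))
    x <- apply_along_axis(x, 4L, corr_operator(kernel$temporal_1d,
                                               kernel$offsets, d[4], "same",
                                               renorm = "ramp"))
    dynamic_image(x, img$grid,
                  frame_indices = img$frame_indices,
                  voxel_size_mm = img$voxel_size_mm,
                  spatial_offset = img$spatial_offset)
  }
}

# 3-D Gaussian blur of every frame, "same" geometry, edge-renormalised.
# sigma_vox: per-axis standard deviation in voxels (0 -> identity).
gaussian_blur4d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    off <- seq.int(-half, half)
    g <- exp(-off^2 / (2 * s^2))
    g <- g / sum(g)
    x <- apply_along_axis(x, ax, corr_operator(g, off, d[ax], "same",
                                               renorm = "sum"))
  }
  x
}

#' Voxelwise temporal mean, SD and coefficient of variation
#'
#' Summarises signal variability over the frames of a dynamic image:
#' voxelwise temporal mean, standard deviation, and coefficient of
#' variation (SD / mean). Voxels with zero temporal mean get `NA` CoV
#' rather than an infinite value.
#'
#' @param img a [dynamic_image()] with at least 2 frames.
#' @return List of three 3-D arrays: `mean`, `sd`, `cov`.
#' @export
describe_variability <- function(img) {
  stopifnot(inherits(img, "dynamic_image"))
  d <- dim(img$data)
  if (d[4] < 2L)
    stop("variability maps need at least 2 frames", call. = FALSE)
  m <- matrix(img$data, prod(d[1:3]), d[4])
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (d[4] - 1))
  cov <- ifelse(mu == 0, NA_real_, sdv / mu)
  out <- list(mean = mu, sd = sdv, cov = cov)
  lapply(out, function(v) { dim(v) <- d[1:3]; v })
}
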