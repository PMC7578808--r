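#' Build the spatio-temporal gradient kernel
#'
#' The filter that converts cumulative glucose uptake into an instantaneous
#' uptake-change signal is the separable product of an isotropic 3-D spatial
#' Gaussian (standard deviation `sigma_spatial_vox` voxels) and an odd,
#' derivative-like temporal profile: a 1-D Gaussian of standard deviation
#' `sigma_temporal_frames` frames, signed so that weights on prior frames
#' are negative, the current frame is exactly zero, and future frames are
#' positive. The kernel is truncated to a `window_extent`^4 window
#' (default 7 x 7 x 7 x 7). The spatial lobe is renormalised to unit sum
#' over its truncated support, and the whole kernel is scaled so that its
#' response to a unit-slope temporal ramp `u(x, y, z, t) = t` is exactly 1;
#' the filter output is therefore interpretable as uptake change per frame.
#'
#' @param sigma_spatial_vox spatial standard deviation in voxels (> 0,
#'   default 1).
#' @param sigma_temporal_frames temporal standard deviation in frames (> 0,
#'   default 2).
#' @param window_extent odd window size >= 3 applied along every axis
#'   (default 7).
#' @return A `gradient_kernel` object: list with the 4-D `weights` array,
#'   the 1-D factors `spatial_1d` and `temporal_1d`, the offsets vector,
#'   and the parameters.
#' @examples
#' k <- build_gradient_kernel()
#' dim(k$weights)          # 7 7 7 7
#' sum(k$weights)          # 0: antisymmetric in time
#' @export
build_gradient_kernel <- function(sigma_spatial_vox = 1,
                                  sigma_temporal_frames = 2,
                                  window_extent = 7) {
  stopif_not_scalar(sigma_spatial_vox, "sigma_spatial_vox", positive = TRUE)
  stopif_not_scalar(sigma_temporal_frames, "sigma_temporal_frames",
                    positive = TRUE)
  stopif_not_scalar(window_extent, "window_extent")
  if (window_extent < 3 || window_extent %% 2 != 1)
    stop("window_extent must be an odd integer >= 3", call. = FALSE)
  half <- (window_extent - 1) / 2
  off <- seq.int(-half, half)

  gs <- exp(-off^2 / (2 * sigma_spatial_vox^2))
  gs <- gs / sum(gs)  # unit-sum truncated spatial lobe (per axis)

  gt <- sign(off) * exp(-off^2 / (2 * sigma_temporal_frames^2))
  ramp <- sum(gt * off)  # response of the temporal profile to u(t) = t
  gt <- gt / ramp        # unit ramp response

  w <- outer(outer(outer(gs, gs), gs), gt)
  dim(w) <- rep(window_extent, 4L)
  structure(list(
    weights = w,
    spatial_1d = gs,
    temporal_1d = gt,
    offsets = as.integer(off),
    sigma_spatial_vox = sigma_spatial_vox,
    sigma_temporal_frames = sigma_temporal_frames,
    window_extent = as.integer(window_extent)
  ), class = "gradient_kernel")
}

#' @export
print.gradient_kernel <- function(x, ...) {
  cat(sprintf(
    "<gradient_kernel> %dx%dx%dx%d, sigma_s = %g vox, sigma_t = %g frames\n",
    x$window_extent, x$window_extent, x$window_extent, x$window_extent,
    x$sigma_spatial_vox, x$sigma_temporal_frames))
  invisible(x)
}

#' Export a gradient kernel as a 4-D NIfTI volume
#'
#' Writes the kernel weights to a NIfTI file so the spatial/temporal weight
#' pattern can be inspected in a viewer.
#'
#' @param kernel a [build_gradient_kernel()] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_kernel_nifti <- function(kernel, path) {
  stopifnot(inherits(kernel, "gradient_kernel"))
  RNifti::writeNifti(kernel$weights, path)
  invisible(path)
}
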