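#' Parcellation container
#'
#' A parcellation assigns each voxel an integer region label; label 0 is
#' background. The study parcellates the brain into 82 regions and applies
#' the same labels to static PET, fPET and fMRI.
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param roi_ids ordered vector of region ids (default: sorted nonzero
#'   labels present).
#' @return A `parcellation` object.
#' @export
parcellation <- function(labels, roi_ids = NULL) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array", call. = FALSE)
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  if (is.null(roi_ids)) roi_ids <- present
  roi_ids <- as.integer(roi_ids)
  if (anyDuplicated(roi_ids))
    stop("roi_ids must be distinct", call. = FALSE)
  if (!all(present %in% roi_ids))
    stop("labels contain ids not listed in roi_ids", call. = FALSE)
  structure(list(labels = labels, roi_ids = roi_ids), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcellation> %dx%dx%d voxels, %d ROIs\n",
              d[1], d[2], d[3], length(x$roi_ids)))
  invisible(x)
}

#' Synthetic block parcellation
#'
#' Tiles a voxel grid with `n_roi` contiguous rectangular regions labelled
#' `1..n_roi`, a stand-in for an anatomical atlas at desk scale. The grid
#' is split into near-cubic tiles; every voxel is assigned (no background)
#' unless `margin` voxels are left unlabelled at each face.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param n_roi number of regions (default 82).
#' @param margin background margin in voxels at each face (default 0).
#' @return A [parcellation()].
#' @export
synthetic_parcellation <- function(grid_shape = c(40, 40, 40), n_roi = 82,
                                   margin = 0) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  inner <- grid_shape - 2L * as.integer(margin)
  if (any(inner < 1L)) stop("margin too large for grid", call. = FALSE)
  # choose tile counts per axis with product >= n_roi, near-cubic
  k <- max(1, floor(n_roi^(1 / 3)))
  nx <- k; ny <- k; nz <- ceiling(n_roi / (k * k))
  while (nx * ny * nz < n_roi) nx <- nx + 1L
  cuts <- function(n, parts) {
    b <- floor(seq(0, n, length.out = parts + 1))
    findInterval(seq_len(n) - 1L, b, rightmost.closed = TRUE)
  }
  ix <- cuts(inner[1], nx); iy <- cuts(inner[2], ny); iz <- cuts(inner[3], nz)
  tile <- outer(outer((ix - 1L), (iy - 1L) * nx, "+"),
                (iz - 1L) * nx * ny, "+") + 1L
  # fold tiles beyond n_roi back onto valid labels so exactly n_roi remain
  tile <- ((tile - 1L) %% n_roi) + 1L
  labels <- array(0L, grid_shape)
  labels[margin + seq_len(inner[1]), margin + seq_len(inner[2]),
         margin + seq_len(inner[3])] <- tile
  parcellation(labels, roi_ids = seq_len(n_roi))
}

# crop parcellation labels to match a (possibly trimmed) image
crop_labels <- function(parc, img) {
  d <- dim(img$data)[1:3]
  off <- img$spatial_offset
  pl <- dim(parc$labels)
  if (all(pl == d) && all(off == 0L)) return(parc$labels)
  if (all(off == 0L) || any(off + d > pl))
    stop("parcellation and image shapes are incompatible", call. = FALSE)
  parc$labels[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
              off[3] + seq_len(d[3]), drop = FALSE]
}

#' ROI time-series container
#' @param values n_roi x n_frames numeric matrix.
#' @param roi_ids region ids, one per row.
#' @param frame_mid_s frame midpoint times in seconds (one per column).
#' @param frame_duration_s frame duration in seconds.
#' @param units character unit tag.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(values, roi_ids, frame_mid_s,
                           frame_duration_s, units = "arbitrary") {
  values <- as.matrix(values)
  if (nrow(values) != length(roi_ids))
    stop("row count must equal number of ROI ids", call. = FALSE)
  if (ncol(values) != length(frame_mid_s))
    stop("column count must equal number of frames", call. = FALSE)
  structure(list(values = values, roi_ids = as.integer(roi_ids),
                 frame_mid_s = as.numeric(frame_mid_s),
                 frame_duration_s = frame_duration_s, units = units),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d frames [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' Extract mean ROI time series from a dynamic image
#'
#' Averages voxel intensities within each parcellation region, per frame.
#' If the image was trimmed by "valid"-mode filtering, the parcellation is
#' cropped by the image's stored spatial offset so labels stay aligned.
#' Regions that end up with no voxels are dropped with a warning.
#'
#' @param img a [dynamic_image()].
#' @param parc a [parcellation()] on the acquisition grid.
#' @return A [roi_timeseries()] with one row per surviving ROI.
#' @export
extract_roi_timeseries <- function(img, parc) {
  stopifnot(inherits(img, "dynamic_image"), inherits(parc, "parcellation"))
  lab <- crop_labels(parc, img)
  d <- dim(img$data)
  labv <- as.integer(lab)
  m <- matrix(img$data, prod(d[1:3]), d[4])
  keep <- labv != 0L
  sums <- rowsum(m[keep, , drop = FALSE], labv[keep])
  counts <- tabulate(labv[keep], nbins = max(parc$roi_ids))
  got <- as.integer(rownames(sums))
  missing <- setdiff(parc$roi_ids, got)
  if (length(missing))
    warning("dropping empty ROI(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
  ids <- parc$roi_ids[parc$roi_ids %in% got]
  vals <- sums[match(ids, got), , drop = FALSE] / counts[ids]
  roi_timeseries(vals, ids, frame_times(img), img$grid$frame_duration_s)
}

#' High-pass filter ROI time series (slow-drift removal)
#'
#' Removes fluctuations slower than `cutoff_hz` by projecting each row onto
#' a discrete-cosine slow-drift basis (plus intercept) and subtracting the
#' projection — the standard drift-removal step for BOLD data (> 0.01 Hz
#' retained). Output rows have mean zero.
#'
#' @param ts a [roi_timeseries()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01); must be below
#'   the Nyquist frequency `1 / (2 tr_s)`.
#' @param tr_s sampling interval (repetition time) in seconds
#'   (default 2.45).
#' @return A [roi_timeseries()] of the same shape, zero-mean rows.
#' @export
highpass_fmri <- function(ts, cutoff_hz = 0.01, tr_s = 2.45) {
  stopifnot(inherits(ts, "roi_timeseries"))
  stopif_not_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  stopif_not_scalar(tr_s, "tr_s", positive = TRUE)
  if (cutoff_hz >= 1 / (2 * tr_s))
    stop("cutoff_hz must be below the Nyquist frequency", call. = FALSE)
  n <- ncol(ts$values)
  k_max <- floor(2 * n * tr_s * cutoff_hz)  # DCT components below cutoff
  x <- ts$values - rowMeans(ts$values)
  if (k_max >= 1) {
    tgrid <- seq_len(n) - 0.5
    B <- sapply(seq_len(k_max), function(k) cos(pi * k * tgrid / n))
    B <- qr.Q(qr(matrix(B, nrow = n)))
    x <- x - (x %*% B) %*% t(B)
  }
  out <- ts
  out$values <- x
  out$units <- paste0(ts$units, " (high-passed)")
  out
}

#' Connectivity matrix container
#'
#' @param values square numeric matrix of correlations; the diagonal is
#'   zeroed by convention.
#' @param roi_ids region ids in row/column order.
#' @param modality one of `"fpet"`, `"fmri"`, `"static_covariance"`.
#' @param aggregation `"subject"` or `"group"`.
#' @param block optional block index.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, roi_ids,
                                modality = c("fpet", "fmri",
                                             "static_covariance"),
                                aggregation = c("subject", "group"),
                                block = NULL) {
  modality <- match.arg(modality)
  aggregation <- match.arg(aggregation)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square", call. = FALSE)
  if (nrow(values) != length(roi_ids))
    stop("roi_ids length must match matrix dimension", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12)
    stop("connectivity matrix must be symmetric", call. = FALSE)
  diag(values) <- 0
  structure(list(values = values, roi_ids = as.integer(roi_ids),
                 modality = modality, aggregation = aggregation,
                 block = block),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %dx%d, %s/%s%s\n",
              nrow(x$values), ncol(x$values), x$modality, x$aggregation,
              if (!is.null(x$block)) sprintf(", block %d", x$block) else ""))
  invisible(x)
}

#' Within-subject ROI-to-ROI connectivity
#'
#' Pearson correlation across frames for every region pair; the diagonal
#' is set to zero by convention.
#'
#' @param ts a [roi_timeseries()] with >= 3 frames.
#' @param modality modality tag for the result (default `"fpet"`).
#' @return A [connectivity_matrix()] tagged `subject`.
#' @export
subject_connectivity <- function(ts, modality = "fpet") {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$values) < 3L)
    stop("connectivity needs at least 3 frames", call. = FALSE)
  v <- apply(ts$values, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI time series: ",
         paste(ts$roi_ids[v == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(t(ts$values))
  r <- (r + t(r)) / 2
  connectivity_matrix(r, ts$roi_ids, modality = modality,
                      aggregation = "subject")
}

#' Group-average connectivity matrices
#'
#' Averages subject-level matrices entrywise on the Fisher-z scale
#' (`atanh`), then transforms back — the standard way to average
#' correlation coefficients. Set `fisher = FALSE` for a plain mean.
#'
#' @param mats list of [connectivity_matrix()] objects sharing `roi_ids`
#'   and modality.
#' @param fisher use the Fisher z transform (default `TRUE`).
#' @return A [connectivity_matrix()] tagged `group`.
#' @export
group_average <- function(mats, fisher = TRUE) {
  if (length(mats) == 0L) stop("need at least one matrix", call. = FALSE)
  stopifnot(all(vapply(mats, inherits, logical(1), "connectivity_matrix")))
  mod <- unique(vapply(mats, `[[`, character(1), "modality"))
  if (length(mod) != 1L)
    stop("cannot average matrices of mixed modality: ",
         paste(mod, collapse = ", "), call. = FALSE)
  ids <- mats[[1]]$roi_ids
  if (!all(vapply(mats, function(m) identical(m$roi_ids, ids), logical(1))))
    stop("matrices have differing roi_ids", call. = FALSE)
  arr <- vapply(mats, `[[`, matrix(0, length(ids), length(ids)), "values")
  arr <- array(arr, dim = c(length(ids), length(ids), length(mats)))
  if (fisher) {
    avg <- tanh(apply(atanh(arr), c(1, 2), mean))
  } else {
    avg <- apply(arr, c(1, 2), mean)
  }
  avg[!is.finite(avg)] <- sign(avg[!is.finite(avg)])  # guards r = +-1 input
  diag(avg) <- 0
  connectivity_matrix((avg + t(avg)) / 2, ids, modality = mod,
                      aggregation = "group")
}

#' Static PET image (sum over frames)
#'
#' Derives a single static image by summing the dynamic frames voxelwise,
#' as done to obtain static PET from the 16-s volumes.
#'
#' @param img a [dynamic_image()].
#' @return A 3-D array.
#' @export
static_image <- function(img) {
  stopifnot(inherits(img, "dynamic_image"))
  d <- dim(img$data)
  out <- rowSums(matrix(img$data, prod(d[1:3]), d[4]))
  dim(out) <- d[1:3]
  out
}

#' Across-subject static metabolic covariance
#'
#' Classic static-PET "connectivity": each subject's regional uptake
#' vector is demeaned (its mean over regions subtracted), then every pair
#' of regions is correlated across subjects.
#'
#' @param static_roi_values subjects x ROI numeric matrix of static
#'   regional uptake.
#' @param roi_ids region ids (default: column count order).
#' @return A [connectivity_matrix()] with modality `static_covariance`,
#'   aggregation `group`.
#' @export
metabolic_covariance <- function(static_roi_values, roi_ids = NULL) {
  m <- as.matrix(static_roi_values)
  if (nrow(m) < 3L)
    stop("metabolic covariance needs at least 3 subjects", call. = FALSE)
  if (is.null(roi_ids)) roi_ids <- seq_len(ncol(m))
  m <- m - rowMeans(m)  # per-subject global demeaning
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI column(s): ",
         paste(roi_ids[v == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(m)
  connectivity_matrix((r + t(r)) / 2, roi_ids,
                      modality = "static_covariance", aggregation = "group")
}

#' Block-wise connectome stability
#'
#' Splits the analysis window into `n_blocks` consecutive blocks, computes
#' per-block connectivity, and reports each block matrix's similarity to
#' the full-window matrix (Pearson correlation of strict upper triangles).
#' Frames are assigned to the block containing their midpoint; blocks are
#' anchored at the start time of the first frame of the series, which for
#' 225 16-s frames over six 10-min blocks yields the deterministic sizes
#' 37, 38, 37, 38, 37, 38.
#'
#' @param ts a [roi_timeseries()] spanning all blocks.
#' @param n_blocks number of blocks (default 6).
#' @param block_duration_s block duration in seconds (default 600).
#' @param modality modality tag for the block matrices.
#' @return List with `block_matrices` (list of [connectivity_matrix()]),
#'   `similarity` (numeric, one entry per block), `block_sizes`, and
#'   `full_matrix`.
#' @export
block_stability <- function(ts, n_blocks = 6, block_duration_s = 600,
                            modality = "fpet") {
  stopifnot(inherits(ts, "roi_timeseries"))
  anchor <- ts$frame_mid_s[1] - ts$frame_duration_s / 2  # first frame start
  b <- floor((ts$frame_mid_s - anchor) / block_duration_s)
  if (any(b < 0) || any(b >= n_blocks))
    stop("frames fall outside the requested blocks", call. = FALSE)
  sizes <- tabulate(b + 1L, nbins = n_blocks)
  if (any(sizes < 3L))
    stop("every block needs at least 3 frames", call. = FALSE)
  full <- subject_connectivity(ts, modality = modality)
  mats <- vector("list", n_blocks)
  sim <- numeric(n_blocks)
  for (k in seq_len(n_blocks)) {
    sub <- ts
    sub$values <- ts$values[, b == (k - 1L), drop = FALSE]
    sub$frame_mid_s <- ts$frame_mid_s[b == (k - 1L)]
    mk <- subject_connectivity(sub, modality = modality)
    mk$block <- k
    mats[[k]] <- mk
    sim[k] <- matrix_similarity(mk, full)
  }
  list(block_matrices = mats, similarity = sim,
       block_sizes = as.integer(sizes), full_matrix = full)
}

#' Sweep gradient-filter widths and summarise connectivity consistency
#'
#' Reruns filter -> parcellation -> connectivity over a grid of spatial and
#' temporal standard deviations and summarises, for each pair, the matrix
#' similarity to the default-width matrix (sigma_s = 1 voxel, sigma_t = 2
#' frames) and the mean off-diagonal connectivity.
#'
#' @param img a [dynamic_image()] of cumulative uptake (analysis window).
#' @param parc a [parcellation()].
#' @param sigma_s_list spatial standard deviations to test (voxels).
#' @param sigma_t_list temporal standard deviations to test (frames).
#' @param window_extent kernel window (default 7).
#' @param edge_policy edge policy passed to [apply_gradient_filter()].
#' @param reference_sigma length-2 `c(sigma_s, sigma_t)` defining the
#'   reference matrix (default `c(1, 2)`).
#' @return List with `matrices` (named list of [connectivity_matrix()])
#'   and `summary` (data frame: sigma_s, sigma_t, similarity_to_default,
#'   mean_connectivity).
#' @export
sweep_filter_parameters <- function(img, parc, sigma_s_list = 1:3,
                                    sigma_t_list = 1:3, window_extent = 7,
                                    edge_policy = "valid",
                                    reference_sigma = c(1, 2)) {
  if (!length(sigma_s_list) || !length(sigma_t_list))
    stop("parameter lists must be nonempty", call. = FALSE)
  one <- function(ss, st) {
    k <- build_gradient_kernel(ss, st, window_extent)
    g <- apply_gradient_filter(img, k, edge_policy)
    subject_connectivity(extract_roi_timeseries(g, parc), modality = "fpet")
  }
  ref <- one(reference_sigma[1], reference_sigma[2])
  grid <- expand.grid(sigma_s = sigma_s_list, sigma_t = sigma_t_list)
  mats <- vector("list", nrow(grid))
  sim <- mc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- one(grid$sigma_s[i], grid$sigma_t[i])
    mats[[i]] <- m
    sim[i] <- matrix_similarity(m, ref)
    mc[i] <- mean_offdiag(m)
  }
  names(mats) <- sprintf("s%g_t%g", grid$sigma_s, grid$sigma_t)
  list(matrices = mats,
       summary = data.frame(sigma_s = grid$sigma_s, sigma_t = grid$sigma_t,
                            similarity_to_default = sim,
                            mean_connectivity = mc))
}
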