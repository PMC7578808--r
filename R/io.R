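#' Write a dynamic image as NIfTI
#'
#' @param img a [dynamic_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype (default `"float"`, i.e. 32-bit, like
#'   the reconstructed scanner output; use `"double"` for lossless
#'   round-trips).
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(img, path, datatype = "float") {
  stopifnot(inherits(img, "dynamic_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(img$voxel_size_mm, img$grid$frame_duration_s)
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

#' Read a 4-D NIfTI file as a dynamic image
#'
#' @param path NIfTI path.
#' @param grid a [build_frame_grid()] describing the acquisition.
#' @param frame_indices 0-based frame-grid indices of the stored frames
#'   (default: frames `0..n-1`).
#' @return A [dynamic_image()].
#' @export
read_nifti_image <- function(path, grid, frame_indices = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  vox <- RNifti::pixdim(nii)[1:3]
  dynamic_image(arr, grid, frame_indices = frame_indices,
                voxel_size_mm = vox)
}

#' Read a parcellation volume
#'
#' @param path NIfTI path of an integer label volume.
#' @param roi_ids expected region ids (default: labels present).
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, roi_ids = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  storage.mode(arr) <- "integer"
  parcellation(arr, roi_ids)
}

#' Write / read a connectivity matrix as TSV with a JSON sidecar
#'
#' The matrix is written tab-separated with a `roi_id` header row and
#' leading column; a `.json` sidecar records modality, aggregation, block
#' and any extra provenance fields.
#'
#' @param mat a [connectivity_matrix()].
#' @param path output `.tsv` path.
#' @param provenance named list of extra fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(mat, path, provenance = list()) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  df <- data.frame(roi_id = mat$roi_ids, mat$values, check.names = FALSE)
  names(df)[-1] <- as.character(mat$roi_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(modality = mat$modality, aggregation = mat$aggregation,
                 block = mat$block, n_roi = length(mat$roi_ids)),
            provenance)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  ids <- as.integer(df$roi_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  meta_path <- sub("\\.tsv$", ".json", path)
  modality <- "fpet"; aggregation <- "subject"; block <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$modality)) modality <- meta$modality
    if (!is.null(meta$aggregation)) aggregation <- meta$aggregation
    if (!is.null(meta$block)) block <- meta$block
  }
  connectivity_matrix((m + t(m)) / 2, ids, modality = modality,
                      aggregation = aggregation, block = block)
}
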