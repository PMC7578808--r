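#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so generators are bit-reproducible without
#' perturbing the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-subject / per-stage seed from a master seed, kept within
# 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

stopif_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Pearson correlation of the strict upper triangles of two matrices
#'
#' The similarity statistic used to compare connectivity matrices
#' (block-stability and filter-sweep summaries): the correlation of the
#' vectorised off-diagonal upper-triangle entries.
#'
#' @param a,b square numeric matrices of identical dimension (or
#'   `connectivity_matrix` objects).
#' @return A single correlation value.
#' @export
matrix_similarity <- function(a, b) {
  va <- if (inherits(a, "connectivity_matrix")) a$values else a
  vb <- if (inherits(b, "connectivity_matrix")) b$values else b
  if (!all(dim(va) == dim(vb)))
    stop("matrices must have identical dimensions", call. = FALSE)
  ut <- upper.tri(va)
  stats::cor(va[ut], vb[ut])
}

# mean of off-diagonal entries of a square matrix
mean_offdiag <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  mean(v[row(v) != col(v)])
}
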