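# Independent brute-force oracles used to cross-check the optimised paths.
# These are written as plain nested loops / direct formulas and must stay
# independent of the package implementation.

# full 4-D sliding correlation of a kernel with an image, "valid" region
oracle_filter <- function(arr, weights) {
  d <- dim(arr)
  w <- dim(weights)[1]
  od <- d - w + 1L
  out <- array(NA_real_, od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2]))
    for (k in seq_len(od[3])) for (t in seq_len(od[4])) {
      patch <- arr[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1),
                   t:(t + w - 1)]
      out[i, j, k, t] <- sum(patch * weights)
    }
  out
}

# per-ROI mean time series by explicit voxel loops
oracle_roi_means <- function(arr, labels, roi_ids) {
  nf <- dim(arr)[4]
  out <- matrix(NA_real_, length(roi_ids), nf)
  for (r in seq_along(roi_ids)) {
    idx <- which(labels == roi_ids[r])
    for (t in seq_len(nf)) {
      frame <- arr[, , , t]
      out[r, t] <- mean(frame[idx])
    }
  }
  out
}

# mean framewise translational displacement by an explicit loop
oracle_mrd <- function(trace) {
  s <- 0
  for (i in 2:nrow(trace)) {
    d <- trace[i, 4:6] - trace[i - 1, 4:6]
    s <- s + sqrt(sum(d^2))
  }
  s / (nrow(trace) - 1)
}

# least-squares quadratic via explicit normal equations; the time axis is
# rescaled internally for conditioning, then the coefficients mapped back
oracle_quadfit <- function(t, y) {
  s <- max(abs(t))
  u <- t / s
  X <- cbind(1, u, u^2)
  b <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  c(b[1], b[2] / s, b[3] / s^2)
}

# masks for within/between-community entries (strict upper triangle)
community_masks <- function(assignment) {
  same <- outer(assignment, assignment, "==")
  ut <- upper.tri(same)
  list(within = same & ut, between = (!same) & ut)
}

# small fixtures shared across tests
tiny_acq <- function(...) acquisition_spec(grid_shape = c(12, 12, 12),
                                           bold_n_frames = 40, ...)
tiny_net <- function(...) network_spec(n_roi = 8, n_communities = 2,
                                       rho_within = 0.6, rho_between = 0.1,
                                       ...)
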