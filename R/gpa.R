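#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively removes translation (centroids to the origin), rotation
#' (per-configuration orthogonal Procrustes fit to the current mean, SVD
#' solution with reflections forbidden: every fitted rotation has
#' determinant +1) and, optionally, scale (unit centroid size). The mean
#' shape is re-estimated after each sweep and iteration stops when it moves
#' by less than `tol` (root-mean-square over coordinates).
#'
#' Centroid sizes are recorded before any scaling and carried on the result,
#' where they serve as the "facial size" covariate downstream.
#'
#' @param landmarks a [landmark_set()] (raw, i.e. not already aligned —
#'   aligning aligned data is permitted and is a no-op to numerical
#'   precision).
#' @param scale remove scale by dividing each configuration by its centroid
#'   size? Default `TRUE`.
#' @param tol convergence tolerance on the mean shape (default `1e-10`).
#' @param max_iter maximum number of sweeps.
#' @return a list with `aligned` (a `landmark_set` with `aligned = TRUE` and
#'   `centroid_sizes`) and `mean_shape` (L x 3 matrix).
#' @examples
#' cfg <- synth_config(n_individuals = 20, n_landmarks = 64, n_levels = 3)
#' res <- gpa_align(generate_faces(cfg)$faces)
#' res$aligned
#' @export
gpa_align <- function(landmarks, scale = TRUE, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(landmarks, "landmark_set"))
  coords <- landmarks$coords
  n <- dim(coords)[1]; L <- dim(coords)[2]
  if (n < 2) abort("GPA needs at least 2 configurations")

  csz <- numeric(n)
  for (i in seq_len(n)) {
    conf <- coords[i, , ]
    conf <- sweep(conf, 2, colMeans(conf))
    s <- sqrt(sum(conf^2))
    if (s < 1e-12) abort("degenerate configuration: all landmarks coincide")
    csz[i] <- s
    if (scale) conf <- conf / s
    coords[i, , ] <- conf
  }

  mean_shape <- apply(coords, c(2, 3), mean)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      coords[i, , ] <- coords[i, , ] %*% procrustes_rotation(
        coords[i, , ], mean_shape)
    }
    new_mean <- apply(coords, c(2, 3), mean)
    if (scale) new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("GPA did not converge in %d iterations (residual %.3g)",
                  max_iter, delta))
  }
  # canonical orientation: rotate everything so the mean shape sits on its
  # principal axes (deterministic signs, det +1); the output then does not
  # depend on the arbitrary orientation of the input frame
  rot <- principal_axes(mean_shape)
  mean_shape <- mean_shape %*% rot
  for (i in seq_len(n)) coords[i, , ] <- coords[i, , ] %*% rot
  list(aligned = landmark_set(coords, ids = landmarks$ids, aligned = TRUE,
                              centroid_sizes = csz),
       mean_shape = mean_shape)
}

# right-handed principal-axis rotation of an L x 3 configuration; signs are
# fixed from the configuration's own third moments along each axis, a
# quantity that does not depend on the frame the data arrived in
principal_axes <- function(conf) {
  V <- eigen(stats::cov(conf), symmetric = TRUE)$vectors
  y <- conf %*% V
  for (k in 1:2) {
    m3 <- sum(y[, k]^3)
    flip <- if (abs(m3) > 1e-12 * sd(y[, k])^3 * nrow(conf)) {
      m3 < 0
    } else {
      V[which.max(abs(V[, k])), k] < 0 # symmetric shape: any fixed rule
    }
    if (flip) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

# rotation R (det +1) minimizing ||A R - B||_F for centered A, B (L x 3)
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(A, B)) # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# subset a landmark set to a segment's landmarks (keeps alignment flag off:
# a segment extracted from aligned data still needs its own GPA)
subset_landmarks <- function(landmarks, idx) {
  landmark_set(landmarks$coords[, idx, , drop = FALSE],
               ids = landmarks$ids)
}
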