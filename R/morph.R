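#' Carrier-versus-non-carrier morph of one facial segment
#'
#' Aligns the segment's landmarks (segment GPA), computes the mean shape of
#' non-carriers, the carrier-minus-non-carrier mean displacement per landmark
#' multiplied by `exaggeration` (the constant that makes subtle effects
#' visible), and the signed component of that displacement along the local
#' surface normal: positive values are protrusions, negative values
#' depressions. Normals are estimated per landmark from a local plane fit to
#' its nearest neighbours on the non-carrier mean shape, oriented away from
#' the segment centroid.
#'
#' @param faces a raw [landmark_set()].
#' @param hierarchy a `segment_hierarchy`.
#' @param segment_id segment to morph.
#' @param carriers logical carrier flags (length n).
#' @param exaggeration displacement multiplier (default 7).
#' @return a `segment_morph`: tibble with one row per segment landmark —
#'   `landmark`, non-carrier mean `x`, `y`, `z`, exaggerated displacement
#'   `dx`, `dy`, `dz`, and `normal_disp` (signed, mm) — with attributes
#'   `segment_id` and `exaggeration`.
#' @export
morph_export <- function(faces, hierarchy, segment_id, carriers,
                         exaggeration = 7) {
  stopifnot(inherits(faces, "landmark_set"))
  idx <- segment_landmarks(hierarchy, segment_id)
  carriers <- as.logical(carriers)
  stopifnot(length(carriers) == dim(faces)[1])
  al <- gpa_align(subset_landmarks(faces, idx))$aligned
  mean_non <- apply(al$coords[!carriers, , , drop = FALSE], c(2, 3), mean)
  mean_car <- apply(al$coords[carriers, , , drop = FALSE], c(2, 3), mean)
  disp <- (mean_car - mean_non) * exaggeration
  nrm <- surface_normals(mean_non)
  out <- tibble(landmark = idx,
                x = mean_non[, 1], y = mean_non[, 2], z = mean_non[, 3],
                dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
                normal_disp = rowSums(disp * nrm))
  structure(out, segment_id = segment_id, exaggeration = exaggeration,
            class = c("segment_morph", class(out)))
}

# per-landmark unit normals from local plane fits (k nearest neighbours),
# oriented away from the configuration centroid
surface_normals <- function(shape, k = 8) {
  L <- nrow(shape)
  k <- min(k, L - 1)
  cen <- colMeans(shape)
  d2 <- as.matrix(stats::dist(shape))^2
  out <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    nb <- order(d2[i, ])[seq_len(k + 1)] # includes i itself
    P <- shape[nb, , drop = FALSE]
    P <- sweep(P, 2, colMeans(P))
    nv <- eigen(crossprod(P), symmetric = TRUE)$vectors[, 3]
    if (sum(nv * (shape[i, ] - cen)) < 0) nv <- -nv
    out[i, ] <- nv
  }
  out
}

#' Write a morph as an ASCII PLY point cloud
#'
#' Vertices are the non-carrier mean segment shape; a per-vertex `quality`
#' scalar carries the signed normal displacement (protrusion positive) for
#' colouring.
#'
#' @param morph a `segment_morph` from [morph_export()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_morph_ply <- function(morph, path) {
  n <- nrow(morph)
  header <- c("ply", "format ascii 1.0",
              sprintf("comment facemod morph, segment %s, exaggeration %s",
                      attr(morph, "segment_id"), attr(morph, "exaggeration")),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property float quality", "end_header")
  body <- sprintf("%.6f %.6f %.6f %.6f",
                  morph$x, morph$y, morph$z, morph$normal_disp)
  writeLines(c(header, body), path)
  invisible(path)
}
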