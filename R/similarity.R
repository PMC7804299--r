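#' RV-coefficient similarity between landmarks
#'
#' For every pair of landmarks, computes the RV coefficient between their
#' `n x 3` displacement blocks (aligned coordinates minus the mean shape).
#' The RV coefficient is a matrix correlation in `[0, 1]`, invariant to
#' rotations of either block, and equals 1 for identical (or rotated copies
#' of the same) displacement patterns.
#'
#' @param aligned an aligned [landmark_set()] (see [gpa_align()]).
#' @param indices landmark indices to restrict to (default: all).
#' @return an `L' x L'` symmetric similarity matrix with unit diagonal.
#'   Zero-variance landmarks get 0 off-diagonal similarity (reported via a
#'   message).
#' @export
landmark_similarity <- function(aligned, indices = NULL) {
  stopifnot(inherits(aligned, "landmark_set"))
  if (!aligned$aligned) abort("landmark_similarity needs GPA-aligned data")
  coords <- if (is.null(indices)) aligned$coords else
    aligned$coords[, indices, , drop = FALSE]
  n <- dim(coords)[1]; L <- dim(coords)[2]
  X <- flatten_coords(coords)
  X <- sweep(X, 2, colMeans(X)) # displacements from the mean shape
  C2 <- crossprod(X)^2 # squared entries of the 3L x 3L cross-product
  # per-pair sums over 3x3 blocks via a block indicator
  blk <- matrix(0, 3 * L, L)
  blk[cbind(seq_len(3 * L), rep(seq_len(L), each = 3))] <- 1
  S2 <- t(blk) %*% C2 %*% blk # S2[i,j] = ||C_ij||_F^2
  d <- sqrt(diag(S2))
  zero <- d < 1e-24
  d[zero] <- 1
  rv <- S2 / outer(d, d)
  rv[zero, ] <- 0; rv[, zero] <- 0
  diag(rv) <- 1
  if (any(zero)) {
    inform(sprintf("%d zero-variance landmark(s): similarity set to 0",
                   sum(zero)))
  }
  rv
}

#' Spectral bipartition of a similarity matrix
#'
#' Partitions landmarks into two non-empty groups using the normalized
#' graph Laplacian \eqn{L = I - D^{-1/2} S D^{-1/2}}: the sign pattern of the
#' Fiedler vector (eigenvector of the second-smallest eigenvalue) seeds a
#' deterministic 2-means refinement on the 2-dimensional spectral embedding.
#' A disconnected similarity graph is split along connected components first;
#' a degenerate (constant) Fiedler vector falls back to a deterministic
#' index split, with a message either way. Group `a` is the part containing
#' the lowest-index landmark.
#'
#' @param similarity symmetric non-negative similarity matrix (unit diagonal).
#' @param indices optional labels for the rows (default `1..L'`); the return
#'   sets are expressed in these labels.
#' @return list with integer vectors `a` and `b` partitioning `indices`.
#' @export
spectral_bipartition <- function(similarity, indices = NULL) {
  L <- nrow(similarity)
  stopifnot(is.matrix(similarity), ncol(similarity) == L)
  if (L < 4) abort("spectral_bipartition needs at least 4 landmarks")
  if (is.null(indices)) indices <- seq_len(L)

  comp <- graph_components(similarity > 1e-12)
  if (max(comp) > 1) {
    inform("disconnected similarity graph: splitting along components")
    a <- comp == 1
    return(canonical_parts(indices[a], indices[!a]))
  }

  off <- similarity[upper.tri(similarity)]
  if (diff(range(off)) < 1e-12) {
    inform("degenerate similarity (all-equal): deterministic index split")
    half <- ceiling(L / 2)
    return(canonical_parts(indices[seq_len(half)], indices[-seq_len(half)]))
  }

  deg <- rowSums(similarity)
  dis <- 1 / sqrt(pmax(deg, 1e-300))
  lap <- diag(L) - similarity * outer(dis, dis)
  es <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  emb <- es$vectors[, c(L, L - 1)] # two smallest eigenvalues
  fiedler <- emb[, 2]

  if (sd(fiedler) < 1e-10) {
    inform("degenerate Fiedler vector: deterministic index split")
    half <- ceiling(L / 2)
    return(canonical_parts(indices[seq_len(half)], indices[-seq_len(half)]))
  }
  g <- fiedler >= 0
  if (all(g) || !any(g)) g <- fiedler >= median(fiedler)
  if (all(g) || !any(g)) g <- seq_len(L) <= ceiling(L / 2)
  centers <- rbind(colMeans(emb[g, , drop = FALSE]),
                   colMeans(emb[!g, , drop = FALSE]))
  km <- suppressWarnings(stats::kmeans(emb, centers = centers,
                                       iter.max = 100))
  part <- km$cluster == 1
  if (all(part) || !any(part)) part <- g # k-means collapsed: keep seeding
  canonical_parts(indices[part], indices[!part])
}

canonical_parts <- function(p, q) {
  if (min(q) < min(p)) list(a = sort(q), b = sort(p))
  else list(a = sort(p), b = sort(q))
}

# connected components of an adjacency matrix (logical), label 1 = the
# component containing vertex 1
graph_components <- function(adj) {
  L <- nrow(adj)
  comp <- integer(L)
  cur <- 0L
  for (v in seq_len(L)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
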