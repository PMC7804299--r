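#' Principal component analysis of one facial module
#'
#' PCA of the `n x (3|segment|)` matrix of centered, segment-GPA-aligned
#' coordinates. All positive-variance components are returned; retention is
#' decided separately by [parallel_analysis()]. Loadings are column
#' orthonormal; scores are mutually uncorrelated; total coordinate variance
#' is conserved by the eigenvalues. A deterministic sign convention (largest
#' absolute loading entry positive) makes the decomposition invariant to
#' global rotations of the input coordinates.
#'
#' @param aligned an aligned [landmark_set()] restricted to the segment
#'   (see [gpa_align()]).
#' @param segment_id identifier carried through to results.
#' @return a `module_phenotype`: list with `segment_id`, `scores` (n x K),
#'   `eigenvalues`, `loadings` (3|segment| x K), `center`, `ids`,
#'   `adjusted = FALSE`.
#' @export
module_pca <- function(aligned, segment_id = NA_integer_) {
  stopifnot(inherits(aligned, "landmark_set"))
  if (!aligned$aligned) abort("module_pca needs segment-GPA-aligned data")
  X <- flatten_coords(aligned$coords)
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- ev > max(ev) * 1e-12
  if (sum(keep) < length(ev)) {
    inform(sprintf("module %s: rank-deficient, %d of %d components kept",
                   segment_id, sum(keep), length(ev)))
  }
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each column positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  structure(list(segment_id = segment_id,
                 scores = U %*% diag(d, nrow = length(d)),
                 eigenvalues = ev[keep], loadings = V, center = ctr,
                 ids = aligned$ids, adjusted = FALSE),
            class = "module_phenotype")
}

#' @export
print.module_phenotype <- function(x, ...) {
  cat(sprintf("<module_phenotype> segment %s: %d individuals x %d PCs (%s)\n",
              x$segment_id, nrow(x$scores), ncol(x$scores),
              if (x$adjusted) "covariate-adjusted" else "raw"))
  invisible(x)
}

#' Parallel analysis for principal component retention
#'
#' Compares the observed covariance eigenvalues of `data` against the
#' position-wise `percentile` of eigenvalues obtained from `n_perm`
#' column-permuted copies (each column permuted independently, destroying
#' correlation while keeping marginals). The number of retained components
#' is the length of the leading run of observed eigenvalues exceeding their
#' permutation threshold, floored at 1.
#'
#' @param data numeric matrix (observations x variables).
#' @param n_perm number of permutations (default 100).
#' @param percentile permutation quantile used as the retention threshold
#'   (default 0.95).
#' @param seed integer seed for the permutation stream.
#' @return integer `K >= 1`, with attribute `"thresholds"` (the permutation
#'   quantiles) and `"eigenvalues"` (observed).
#' @export
parallel_analysis <- function(data, n_perm = 100, percentile = 0.95,
                              seed = 1L) {
  stopifnot(is.matrix(data), n_perm >= 1)
  n <- nrow(data); d <- ncol(data)
  obs <- cov_eigenvalues(sweep(data, 2, colMeans(data)))
  r <- length(obs)
  perm_ev <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Xp <- apply(data, 2, sample)
      ev <- cov_eigenvalues(sweep(Xp, 2, colMeans(Xp)))
      length(ev) <- r # pad/truncate to the observed rank
      ev
    }, numeric(r))
  })
  perm_ev[is.na(perm_ev)] <- 0
  thr <- apply(perm_ev, 1, quantile, probs = percentile, names = FALSE)
  above <- obs > thr
  k <- if (!above[1]) 1L else {
    runs <- rle(above)
    max(1L, runs$lengths[1])
  }
  structure(as.integer(k), thresholds = thr, eigenvalues = obs)
}

# eigenvalues of cov(X) for centered X, via the smaller Gram matrix
cov_eigenvalues <- function(Xc) {
  n <- nrow(Xc); d <- ncol(Xc)
  G <- if (n <= d) tcrossprod(Xc) else crossprod(Xc)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values / (n - 1)
  ev[ev > max(ev, 0) * 1e-12 & ev > 0]
}

#' Residualize module scores on covariates
#'
#' Removes the linear effect of every covariate column from the PC scores.
#' With the number of latent components equal to the rank of the covariate
#' matrix, partial-least-squares residualization coincides with least-squares
#' projection, which is what is computed (QR-based): the returned scores are
#' exactly orthogonal to every covariate column. Constant covariate columns
#' are dropped with a warning.
#'
#' @param phenotype a `module_phenotype`.
#' @param covariates a data frame whose first column is `id`; remaining
#'   numeric columns are removed from the scores. Row order may differ from
#'   the phenotype; rows are matched by id.
#' @return the adjusted `module_phenotype` (`adjusted = TRUE`).
#' @export
pls_adjust <- function(phenotype, covariates) {
  stopifnot(inherits(phenotype, "module_phenotype"))
  covariates <- as.data.frame(covariates)
  m <- match(phenotype$ids, covariates[[1]])
  if (anyNA(m)) abort("covariate ids do not cover the phenotype ids")
  X <- as.matrix(covariates[m, -1, drop = FALSE])
  if (!is.numeric(X)) abort("covariate columns must be numeric")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warn(sprintf("dropping constant covariate column(s): %s",
                 paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  Xd <- cbind(1, scale(X))
  qrX <- qr(Xd)
  res <- qr.resid(qrX, phenotype$scores)
  if (all(abs(res) < 1e-12)) {
    warn("phenotype fully explained by covariates: residuals are zero")
  }
  phenotype$scores <- res
  phenotype$adjusted <- TRUE
  phenotype
}

#' Robust Mahalanobis outlier screen for a module phenotype
#'
#' Computes squared Mahalanobis distances of the PC scores from a robust
#' (minimum covariance determinant) center and covariance, flags individuals
#' exceeding the chi-square quantile at `1 - alpha/n` (Bonferroni-style,
#' `df = K`), and exports the Q-Q pairing of chi-square quantiles versus
#' ordered distances for visual review.
#'
#' @param phenotype a `module_phenotype`.
#' @param alpha family-wise flagging level (default 0.05).
#' @return a tibble (`id`, `dist2`, `flag`) with attributes `threshold`,
#'   `estimator` (`"mcd"` or `"classical"`) and `qq` (tibble with
#'   `chisq_quantile`, `dist2`).
#' @export
mahalanobis_outliers <- function(phenotype, alpha = 0.05) {
  stopifnot(inherits(phenotype, "module_phenotype"))
  S <- phenotype$scores
  n <- nrow(S); K <- ncol(S)
  if (n <= 5 * K) {
    warn(sprintf("n = %d is small for K = %d dimensions; MCD may be unstable",
                 n, K))
  }
  est <- "mcd"
  rob <- tryCatch(MASS::cov.rob(S, method = "mcd"),
                  error = function(e) NULL)
  if (is.null(rob) || min(eigen(rob$cov, symmetric = TRUE,
                                only.values = TRUE)$values) < 1e-12) {
    inform("robust covariance singular or unavailable: classical estimate")
    est <- "classical"
    rob <- list(center = colMeans(S), cov = cov(S))
  }
  d2 <- mahalanobis(S, rob$center, rob$cov)
  thr <- qchisq(1 - alpha / n, df = K)
  ord <- order(d2)
  qq <- tibble(
    chisq_quantile = qchisq((seq_len(n) - 0.5) / n, df = K),
    dist2 = d2[ord], id = phenotype$ids[ord])
  out <- tibble(id = phenotype$ids, dist2 = d2, flag = d2 > thr)
  attr(out, "threshold") <- thr
  attr(out, "estimator") <- est
  attr(out, "qq") <- qq
  out
}
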