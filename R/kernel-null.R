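# Null multivariate model and score algebra for the gene-based kernel tests.

#' Fit the null multivariate regression for a module phenotype
#'
#' Least-squares fit of the `n x K` matrix of module PC scores on the test
#' covariates. Because covariate adjustment happens at the phenotyping stage,
#' `X` defaults to an intercept only. The residual matrix, residual
#' covariance `Sigma = R'R / (n - p)` and the covariate projector (held as a
#' QR factorization, applied on demand) form the ingredients of every score
#' statistic downstream.
#'
#' @param y numeric `n x K` matrix of phenotype scores (a
#'   `module_phenotype`'s `scores`, or any matrix).
#' @param x covariate matrix including the intercept column; `NULL` (default)
#'   means intercept only. Collinear columns are dropped with a warning.
#' @return a `kernel_null_model`: list with `residuals` (n x K), `sigma`,
#'   `sigma_inv`, `qr_x`, `n`, `p`, `df`, `regularized`.
#' @export
fit_null <- function(y, x = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); K <- ncol(y)
  if (is.null(x)) x <- matrix(1, n, 1)
  x <- as.matrix(x)
  if (nrow(x) != n) abort("covariates and phenotypes disagree on n")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warn(sprintf("covariate matrix rank-deficient: %d of %d columns used",
                 qx$rank, ncol(x)))
  }
  p <- qx$rank
  if (n <= p + K) abort("need n > p + K for a stable null fit")
  r <- qr.resid(qx, y)
  sigma <- crossprod(r) / (n - p)
  if (max(abs(sigma)) < 1e-20) {
    abort("degenerate null model: phenotype exactly explained by covariates")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  regularized <- FALSE
  if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > 1e10) {
    inform("residual covariance near-singular: ridge regularization applied")
    sigma <- sigma + diag(1e-8 * mean(diag(sigma)), K)
    regularized <- TRUE
  }
  structure(list(residuals = r, sigma = sigma, sigma_inv = solve(sigma),
                 qr_x = qx, n = n, p = p, df = n - p,
                 regularized = regularized),
            class = "kernel_null_model")
}

#' Variant-by-trait score matrix
#'
#' `S = Gw' R Sigma^{-1}`: row `j` holds the score of weighted variant `j`
#' against each of the K traits, standardized by the inverse residual
#' covariance.
#'
#' @param null a `kernel_null_model`.
#' @param gw weighted dosage matrix `n x m` (rows aligned with the null
#'   model's individuals).
#' @return numeric `m x K` score matrix.
#' @export
score_matrix <- function(null, gw) {
  stopifnot(inherits(null, "kernel_null_model"),
            nrow(gw) == null$n)
  crossprod(gw, null$residuals) %*% null$sigma_inv
}

#' Kernel quadratic-form statistic
#'
#' The four phenotype-by-genotype kernel combinations reduce to quadratic
#' forms in the score matrix: the SKAT genotype kernel aggregates per-variant
#' scores, the burden kernel first collapses them into a single weighted sum
#' (`s_b = colSums(S)`); the heterogeneous phenotype kernel sums squared
#' trait scores (identity cross-trait structure), the homogeneous kernel
#' squares the summed trait score (shared, rank-1 structure).
#'
#' @param s score matrix from [score_matrix()].
#' @param phenotype_kernel `"het"` or `"hom"`.
#' @param genotype_kernel `"skat"` or `"burden"`.
#' @return the scalar Q statistic.
#' @export
q_statistic <- function(s, phenotype_kernel = c("het", "hom"),
                        genotype_kernel = c("skat", "burden")) {
  phenotype_kernel <- match.arg(phenotype_kernel)
  genotype_kernel <- match.arg(genotype_kernel)
  stopifnot(all(is.finite(s)))
  if (genotype_kernel == "burden") {
    s <- matrix(colSums(s), nrow = 1)
  }
  if (phenotype_kernel == "het") sum(s^2) else sum(rowSums(s)^2)
}

#' Null eigenvalues of a kernel statistic
#'
#' Under the null, `vec(S) ~ N(0, Sigma^{-1} (x) Gw' P0 Gw)` and each Q is a
#' quadratic form in it, so its null law is a mixture of independent 1-df
#' chi-squares with weights given by products `a_i * b_l`: `a_i` are the
#' eigenvalues of `Sigma_P Sigma^{-1}` (with `Sigma_P = I` for the
#' heterogeneous kernel, the all-ones matrix — a single non-zero eigenvalue
#' `1' Sigma^{-1} 1` — for the homogeneous kernel) and `b_l` the eigenvalues
#' of `Gw' P0 Gw` (SKAT) or the scalar `1' Gw' P0 Gw 1` (burden).
#'
#' @param null a `kernel_null_model`.
#' @param gw weighted dosage matrix.
#' @param phenotype_kernel,genotype_kernel kernel choice as in
#'   [q_statistic()].
#' @param gpg optional precomputed `Gw' P0 Gw` (shared across kernels).
#' @return numeric vector of positive eigenvalues (negligible ones, below
#'   `1e-10` of the largest, dropped); `numeric(0)` when the projected
#'   genotypes carry no variance.
#' @export
null_eigenvalues <- function(null, gw,
                             phenotype_kernel = c("het", "hom"),
                             genotype_kernel = c("skat", "burden"),
                             gpg = NULL) {
  phenotype_kernel <- match.arg(phenotype_kernel)
  genotype_kernel <- match.arg(genotype_kernel)
  if (is.null(gpg)) gpg <- genotype_gram(null, gw)
  a <- if (phenotype_kernel == "het") {
    eigen(null$sigma_inv, symmetric = TRUE, only.values = TRUE)$values
  } else {
    sum(null$sigma_inv)
  }
  b <- if (genotype_kernel == "skat") {
    eigen(gpg, symmetric = TRUE, only.values = TRUE)$values
  } else {
    sum(gpg)
  }
  lam <- as.vector(outer(a, b))
  lam <- lam[lam > 0]
  if (!length(lam)) return(numeric(0))
  lam[lam >= 1e-10 * max(lam)]
}

# Gw' P0 Gw via the null model's covariate projector
genotype_gram <- function(null, gw) {
  crossprod(qr.resid(null$qr_x, gw))
}
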