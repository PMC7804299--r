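# Copula minP omnibus over the 2x2 kernel combinations.

KERNELS <- list(
  hom_skat = c("hom", "skat"), het_skat = c("het", "skat"),
  hom_burden = c("hom", "burden"), het_burden = c("het", "burden"))

#' Omnibus minimum-p test across the four kernel combinations
#'
#' The four kernel p-values are dependent (same data, related statistics).
#' The omnibus takes `T = min(p)` and calibrates it under a Gaussian copula:
#' the 4x4 correlation of the probit-transformed p-values is estimated from
#' `B` null resamples of the score matrix (drawn directly from its null law
#' `vec(S) ~ N(0, Sigma^{-1} (x) Gw'P0Gw)`, equivalent to resampling residual
#' rows from `N(0, Sigma)`), and
#' `p_omnibus = 1 - P(all four probit(1 - p_i) <= probit(1 - T))`
#' under that correlation. Perfectly dependent kernels give `p_omnibus = T`;
#' independent kernels give `1 - (1 - T)^4`.
#'
#' @param p_values named numeric vector of the four kernel p-values
#'   (`hom_skat`, `het_skat`, `hom_burden`, `het_burden`).
#' @param null a `kernel_null_model`.
#' @param gw weighted dosage matrix of the gene.
#' @param B number of null resamples (minimum 50; default 500).
#' @param seed integer seed for the resampling stream.
#' @param gpg optional precomputed `Gw'P0Gw`.
#' @return list with `p_omnibus`, `t_min`, and `correlation` (the estimated
#'   4x4 probit correlation).
#' @export
omnibus_minp <- function(p_values, null, gw, B = 500, seed = 1L,
                         gpg = NULL) {
  stopifnot(length(p_values) == 4, all(is.finite(p_values)))
  if (B < 50) abort("B < 50 resamples gives an unstable copula correlation")
  if (is.null(gpg)) gpg <- genotype_gram(null, gw)
  z <- null_probit_scores(null, gpg, B = B, seed = seed)
  rho <- copula_correlation(z)
  t_min <- min(p_values)
  p_om <- copula_minp(t_min, rho, seed = seed)
  list(p_omnibus = p_om, t_min = t_min, correlation = rho)
}

# B x 4 matrix of probit-transformed null kernel p-values; resamples the
# score matrix from its exact null MVN law, vectorized across replicates.
# Liu moment matching is used for the resample p-values (only their probit
# correlation is consumed).
null_probit_scores <- function(null, gpg, B, seed) {
  K <- ncol(null$sigma_inv)
  m <- nrow(gpg)
  lam <- list(
    hom_skat = null_eigenvalues(null, NULL, "hom", "skat", gpg = gpg),
    het_skat = null_eigenvalues(null, NULL, "het", "skat", gpg = gpg),
    hom_burden = null_eigenvalues(null, NULL, "hom", "burden", gpg = gpg),
    het_burden = null_eigenvalues(null, NULL, "het", "burden", gpg = gpg))
  eg <- eigen(gpg, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m) # A A' = gpg
  Bu <- chol(null$sigma_inv) # Bu' Bu = Sigma^{-1}
  with_seed(seed, {
    Z <- matrix(rnorm(m * K * B), m, K * B)
    W <- A %*% Z # m x (K*B), cov over columns independent
    # reorder to (m*B) x K blocks and apply the trait factor
    S_all <- matrix(aperm(array(W, c(m, K, B)), c(1, 3, 2)), m * B, K) %*% Bu
    grp <- rep(seq_len(B), each = m)
    q_het_skat <- rowsum(rowSums(S_all^2), grp)[, 1]
    q_hom_skat <- rowsum(rowSums(S_all)^2, grp)[, 1]
    sb <- rowsum(S_all, grp) # B x K collapsed scores
    q_het_burden <- rowSums(sb^2)
    q_hom_burden <- rowSums(sb)^2
    qs <- cbind(hom_skat = q_hom_skat, het_skat = q_het_skat,
                hom_burden = q_hom_burden, het_burden = q_het_burden)
    z <- qs
    for (k in colnames(qs)) {
      p <- vapply(qs[, k], liu_tail, numeric(1), lambda = lam[[k]])
      p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
      z[, k] <- qnorm(p, lower.tail = FALSE)
    }
    z
  })
}

# correlation of probit scores, coerced to a usable PD matrix
copula_correlation <- function(z) {
  rho <- suppressWarnings(cor(z))
  rho[!is.finite(rho)] <- 1 # degenerate columns (constant p) are identical
  rho <- (rho + t(rho)) / 2
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    v <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    rho <- stats::cov2cor(rho)
  }
  rho
}

# 1 - P(all Z_i <= qnorm(1 - t)) under N(0, rho); quasi-MC rectangle
# probability with a locally fixed seed so results are reproducible
copula_minp <- function(t_min, rho, seed = 1L) {
  zt <- qnorm(t_min, lower.tail = FALSE)
  if (!is.finite(zt)) return(t_min)
  pr <- with_seed(stage_seed(seed, "mvncdf"), {
    mvtnorm::pmvnorm(lower = rep(-Inf, nrow(rho)),
                     upper = rep(zt, nrow(rho)), corr = rho,
                     algorithm = mvtnorm::GenzBretz(abseps = 1e-9,
                                                    maxpts = 100000))
  })
  p <- 1 - as.numeric(pr)
  if (p < 1e-8) {
    # below the resolution of the rectangle probability: use the
    # independence (Bonferroni-like, conservative) combination instead
    p <- -expm1(4 * log1p(-t_min))
  }
  min(max(p, t_min), 1)
}
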