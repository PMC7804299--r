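# Null model, score algebra, kernel statistics, mixture-chi-square engine.

test_that("intercept-only null model reduces to centered-data moments", {
  set.seed(1)
  Y <- matrix(rnorm(100 * 3), 100, 3)
  null <- fit_null(Y)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(null$residuals, Yc, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(null$sigma, crossprod(Yc) / 99, tolerance = 1e-12)
  expect_equal(null$df, 99)
})

test_that("a phenotype exactly explained by covariates is degenerate", {
  set.seed(2)
  X <- cbind(1, rnorm(50))
  Y <- X %*% matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(fit_null(Y, X), "degenerate")
})

test_that("residual covariance of orthogonal PC scores is diagonal", {
  ph <- suppressMessages(module_pca(aligned_small(), segment_id = 1L))
  null <- fit_null(ph$scores[, 1:10])
  off <- null$sigma
  diag(off) <- 0
  expect_lt(max(abs(off)) / min(diag(null$sigma)), 1e-8)
})

test_that("score matrix matches an explicit per-variant, per-trait loop", {
  set.seed(3)
  n <- 60; m <- 4; K <- 3
  Y <- matrix(rnorm(n * K), n, K)
  Gw <- matrix(rbinom(n * m, 2, 0.1) * runif(m)[col(matrix(0, n, m))], n, m)
  null <- fit_null(Y)
  S <- score_matrix(null, Gw)
  Sinv <- solve(null$sigma)
  oracle <- matrix(0, m, K)
  for (j in 1:m) for (k in 1:K) {
    for (l in 1:K) {
      oracle[j, k] <- oracle[j, k] +
        sum(Gw[, j] * null$residuals[, l]) * Sinv[l, k]
    }
  }
  expect_equal(S, oracle, tolerance = 1e-10)
})

test_that("genotypes orthogonal to the residuals give a zero score", {
  set.seed(4)
  n <- 40
  Y <- matrix(rnorm(n), n, 1)
  null <- fit_null(Y)
  g <- rep(1, n) # in the intercept column space: projected out
  S <- score_matrix(null, qr.resid(null$qr_x, matrix(g)))
  expect_lt(max(abs(S)), 1e-10)
})

test_that("kernel statistics match hand arithmetic on a 2x2 score matrix", {
  S <- matrix(c(1, 3, 2, 4), 2, 2) # rows: variants; cols: traits
  expect_equal(q_statistic(S, "het", "skat"), 30) # 1+9+4+16
  expect_equal(q_statistic(S, "hom", "skat"), 58) # 3^2 + 7^2
  expect_equal(q_statistic(S, "het", "burden"), 52) # 4^2 + 6^2
  expect_equal(q_statistic(S, "hom", "burden"), 100) # (4+6)^2
  expect_equal(q_statistic(matrix(0, 3, 2), "het", "skat"), 0)
})

test_that("with one trait the phenotype kernels coincide", {
  set.seed(5)
  S <- matrix(rnorm(5), 5, 1)
  expect_equal(q_statistic(S, "het", "skat"), q_statistic(S, "hom", "skat"))
  Y <- matrix(rnorm(80), 80, 1)
  null <- fit_null(Y)
  Gw <- matrix(rbinom(80 * 3, 2, 0.1), 80, 3) * 0.7
  expect_equal(null_eigenvalues(null, Gw, "het", "skat"),
               null_eigenvalues(null, Gw, "hom", "skat"), tolerance = 1e-10)
})

test_that("null eigenvalue algebra follows the Kronecker structure", {
  set.seed(6)
  n <- 120; K <- 3; m <- 4
  Y <- matrix(rnorm(n * K), n, K)
  null <- fit_null(Y)
  Gw <- matrix(rbinom(n * m, 2, 0.2), n, m) * 0.5
  gpg <- facemod:::genotype_gram(null, Gw)
  b <- eigen(gpg, symmetric = TRUE, only.values = TRUE)$values
  # hom kernel: single trait-side eigenvalue 1' Sigma^-1 1
  lam_hom <- null_eigenvalues(null, Gw, "hom", "skat")
  expect_equal(sort(lam_hom, decreasing = TRUE),
               sort(sum(null$sigma_inv) * b, decreasing = TRUE),
               tolerance = 1e-8)
  # Sigma = I, het: every b repeated K times
  null_id <- null
  null_id$sigma <- diag(K); null_id$sigma_inv <- diag(K)
  lam_het <- null_eigenvalues(null_id, Gw, "het", "skat")
  expect_equal(sort(lam_het, decreasing = TRUE),
               sort(rep(b, K), decreasing = TRUE), tolerance = 1e-8)
  # burden: genotype side collapses to the scalar 1' Gw'P0Gw 1
  lam_b <- null_eigenvalues(null, Gw, "het", "burden")
  a <- eigen(null$sigma_inv, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(lam_b), sort(a * sum(gpg)), tolerance = 1e-8)
})

test_that("simulated null Q follows the mixture-chi-square law", {
  set.seed(7)
  n <- 150; K <- 2; m <- 3
  Y <- matrix(rnorm(n * K), n, K)
  null <- fit_null(Y)
  Gw <- matrix(rbinom(n * m, 2, 0.15), n, m) * 0.6
  lam <- null_eigenvalues(null, Gw, "het", "skat")
  sigma_chol <- chol(null$sigma)
  draws <- replicate(4000, {
    E <- matrix(rnorm(n * K), n, K) %*% sigma_chol
    null_b <- null
    null_b$residuals <- qr.resid(null$qr_x, E)
    q_statistic(score_matrix(null_b, Gw), "het", "skat")
  })
  # transform through the claimed null law: should be uniform
  u <- vapply(draws, function(q) pvalue_mixture_chisq(q, lam)$p, numeric(1))
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("the mixture engine reproduces chi-square closed forms", {
  for (q in c(0.5, 3.84, 10, 25)) {
    expect_equal(pvalue_mixture_chisq(q, 1)$p,
                 pchisq(q, 1, lower.tail = FALSE), tolerance = 1e-10)
    expect_equal(pvalue_mixture_chisq(q, c(1, 1))$p, exp(-q / 2),
                 tolerance = 1e-10)
  }
  expect_error(pvalue_mixture_chisq(1, numeric(0)), "empty")
})

test_that("the mixture engine agrees with Monte-Carlo for mixed weights", {
  lam <- c(2, 1, 0.5)
  set.seed(8)
  nmc <- 2e5
  draws <- lam[1] * rchisq(nmc, 1) + lam[2] * rchisq(nmc, 1) +
    lam[3] * rchisq(nmc, 1)
  for (q in c(3, 7, 12)) {
    p_hat <- mean(draws > q)
    se <- sqrt(p_hat * (1 - p_hat) / nmc)
    expect_lt(abs(pvalue_mixture_chisq(q, lam)$p - p_hat), 3.5 * se)
  }
})

test_that("spread eigenvalues fall back to CF inversion gracefully", {
  lam <- c(1000, 1, 0.001)
  res <- pvalue_mixture_chisq(1500, lam)
  expect_true(res$method %in% c("ruben", "imhof", "liu"))
  expect_gt(res$p, 0); expect_lte(res$p, 1)
  # sanity against moment matching: same order of magnitude
  expect_equal(res$p, facemod:::liu_tail(1500, lam), tolerance = 0.05)
})
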