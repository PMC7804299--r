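# Module PCA, parallel analysis, covariate residualization, outlier screen.

test_that("PCA conserves variance, reconstructs data, orthonormal loadings", {
  al <- aligned_small()
  ph <- suppressMessages(module_pca(al, segment_id = 1L))
  X <- facemod:::flatten_coords(al$coords)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(ph$eigenvalues), sum(Xc^2) / (nrow(X) - 1),
               tolerance = 1e-10)
  recon <- ph$scores %*% t(ph$loadings)
  expect_lt(max(abs(recon - Xc)), 1e-8)
  expect_equal(crossprod(ph$loadings), diag(ncol(ph$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  cors <- cor(ph$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  expect_true(all(diff(ph$eigenvalues) <= 1e-12))
})

test_that("rank-1 planted variation concentrates in the first component", {
  set.seed(1)
  v <- rnorm(36); v <- v / sqrt(sum(v^2))
  scores <- rnorm(100, sd = 3)
  X <- outer(scores, v) + matrix(rnorm(3600, sd = 0.01), 100, 36)
  coords <- facemod:::unflatten_coords(X, 12)
  al <- landmark_set(coords, aligned = TRUE, centroid_sizes = rep(1, 100))
  ph <- suppressMessages(module_pca(al))
  expect_gt(ph$eigenvalues[1] / sum(ph$eigenvalues), 0.99)
})

test_that("parallel analysis floors at 1 on pure noise", {
  set.seed(2)
  hits <- vapply(1:40, function(i) {
    X <- matrix(rnorm(100 * 20), 100, 20)
    as.integer(parallel_analysis(X, n_perm = 30, seed = i))
  }, integer(1))
  expect_gte(mean(hits == 1), 0.85) # ~95% expected; allow Monte-Carlo slack
})

test_that("parallel analysis finds planted strong components", {
  set.seed(3)
  n <- 300; d <- 30
  B <- qr.Q(qr(matrix(rnorm(d * 5), d, 5)))
  X <- matrix(rnorm(n * 5), n, 5) %*% t(B) * 10 +
    matrix(rnorm(n * d), n, d)
  k <- parallel_analysis(X, n_perm = 50, seed = 4)
  expect_equal(as.integer(k), 5L)
  expect_identical(as.integer(parallel_analysis(X, n_perm = 50, seed = 4)),
                   as.integer(k)) # deterministic under the seed
})

test_that("residualization makes scores exactly orthogonal to covariates", {
  co <- small_cohort()
  ph <- suppressMessages(module_pca(aligned_small(), segment_id = 1L))
  adj <- pls_adjust(ph, co$covariates)
  X <- as.matrix(co$covariates[, -1])
  for (j in seq_len(ncol(X))) {
    expect_lt(max(abs(cor(adj$scores, X[, j]))), 1e-8)
  }
  expect_true(adj$adjusted)
})

test_that("covariates unrelated to shape barely change the scores", {
  set.seed(5)
  ph <- toy_phenotype(n = 500, k = 3)
  cv <- data.frame(id = ph$ids, a = rnorm(500), b = rnorm(500))
  adj <- pls_adjust(ph, cv)
  expect_gt(min(diag(cor(adj$scores, ph$scores))), 0.99)
})

test_that("constant covariates are dropped and full explanation flagged", {
  ph <- toy_phenotype(n = 100, k = 2)
  cv <- data.frame(id = ph$ids, a = rnorm(100), c = 1)
  expect_warning(pls_adjust(ph, cv), "constant")
  ph2 <- ph
  z <- rnorm(100)
  ph2$scores <- cbind(z, 2 * z)
  cv2 <- data.frame(id = ph$ids, z = z)
  expect_warning(pls_adjust(ph2, cv2), "fully explained")
})

test_that("outlier screen flags a gross outlier and spares clean data", {
  set.seed(6)
  ph <- toy_phenotype(n = 400, k = 4)
  out <- suppressWarnings(mahalanobis_outliers(ph, alpha = 0.05))
  expect_lte(sum(out$flag), 2)
  ph$scores[7, 1] <- 10 * sd(ph$scores[, 1]) # displaced individual
  out2 <- suppressWarnings(mahalanobis_outliers(ph, alpha = 0.05))
  expect_true(out2$flag[7])
  qq <- attr(out2, "qq")
  expect_equal(nrow(qq), 400)
  expect_true(all(diff(qq$dist2) >= 0))
})

test_that("Mahalanobis distances are invariant to linear re-expression", {
  set.seed(7)
  ph <- toy_phenotype(n = 300, k = 3)
  A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
  ph2 <- ph
  ph2$scores <- ph$scores %*% A
  set.seed(42)
  d1 <- mahalanobis_outliers(ph)$dist2
  set.seed(42)
  d2 <- mahalanobis_outliers(ph2)$dist2
  expect_equal(d1, d2, tolerance = 1e-6)
})
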