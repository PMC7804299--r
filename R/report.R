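#' RV correlation between module phenotypes
#'
#' Entry (u, v) is the RV coefficient between module u's and module v's
#' retained PC score blocks — the inter-module correlation used for the
#' effective-number-of-tests correction. Partially overlapping modules share
#' landmarks and are therefore correlated; the matrix is symmetric with unit
#' diagonal and is floored to positive semi-definite if numerics dip below
#' zero (with a warning).
#'
#' @param phenotypes a `module_phenotype_set` or named list of
#'   `module_phenotype`.
#' @return a symmetric `n_modules x n_modules` matrix.
#' @export
module_correlation <- function(phenotypes) {
  modules <- if (inherits(phenotypes, "module_phenotype_set")) {
    phenotypes$modules
  } else phenotypes
  nm <- length(modules)
  blocks <- lapply(modules, function(m) scale(m$scores, scale = FALSE))
  cc <- lapply(blocks, crossprod)
  self <- vapply(cc, function(C) sum(C^2), numeric(1))
  out <- diag(nm)
  for (u in seq_len(nm - 1)) {
    for (v in (u + 1):nm) {
      Cuv <- crossprod(blocks[[u]], blocks[[v]])
      out[u, v] <- out[v, u] <- sum(Cuv^2) / sqrt(self[u] * self[v])
    }
  }
  dimnames(out) <- list(names(modules), names(modules))
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warn("module correlation numerically indefinite; eigenvalues floored")
  }
  out
}

#' Effective number of independent tests (eigenvalue-based)
#'
#' From the eigenvalues `lambda_i` of a correlation matrix:
#' `M_eff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#' Equals the dimension for the identity matrix and 1 for an all-ones
#' matrix.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @return the raw (non-integer) M_eff, with attribute `"eigenvalues"`.
#' @examples
#' effective_tests_li_ji(diag(31)) # 31
#' @export
effective_tests_li_ji <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    abort("correlation matrix must be symmetric")
  }
  lam <- eigen((corr + t(corr)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, 0)
  # guard eigenvalues sitting a rounding error below an integer
  fl <- floor(lam + 1e-9)
  meff <- sum((lam >= 1 - 1e-9) + pmax(lam - fl, 0))
  structure(meff, eigenvalues = lam)
}

#' Bonferroni-style significance threshold over genes and effective modules
#'
#' `alpha / (n_genes * m_eff)`; reports print it at two significant figures.
#'
#' @param n_genes number of genes tested.
#' @param m_eff effective number of independent modules.
#' @param alpha family-wise level (default 0.05).
#' @return the threshold (full precision).
#' @examples
#' signif(significance_threshold(8091, 19), 2) # 3.3e-07
#' @export
significance_threshold <- function(n_genes, m_eff, alpha = 0.05) {
  stopifnot(n_genes > 0, m_eff > 0, alpha > 0)
  alpha / (n_genes * m_eff)
}

#' Multiplicity plan for a module scan
#'
#' Combines [module_correlation()], [effective_tests_li_ji()] (reported raw
#' and rounded half-up) and [significance_threshold()].
#'
#' @param phenotypes a `module_phenotype_set`.
#' @param n_genes number of genes tested.
#' @param alpha family-wise level (default 0.05).
#' @return a `multiplicity_plan`: list with `n_genes`, `correlation`,
#'   `eigenvalues`, `m_eff_raw`, `m_eff`, `alpha`, `threshold`.
#' @export
multiplicity_plan <- function(phenotypes, n_genes, alpha = 0.05) {
  corr <- module_correlation(phenotypes)
  meff_raw <- effective_tests_li_ji(corr)
  meff <- max(1L, as.integer(floor(as.numeric(meff_raw) + 0.5)))
  structure(list(n_genes = n_genes, correlation = corr,
                 eigenvalues = attr(meff_raw, "eigenvalues"),
                 m_eff_raw = as.numeric(meff_raw), m_eff = meff,
                 alpha = alpha,
                 threshold = significance_threshold(n_genes, meff, alpha)),
            class = "multiplicity_plan")
}

#' @export
print.multiplicity_plan <- function(x, ...) {
  cat(sprintf(
    "<multiplicity_plan> %d genes x %d effective modules (raw %.2f)\n",
    x$n_genes, x$m_eff, x$m_eff_raw))
  cat(sprintf("  threshold: p < %s  [%g / (%d x %d)]\n",
              format(signif(x$threshold, 2)), x$alpha, x$n_genes, x$m_eff))
  invisible(x)
}

#' Carrier versus non-carrier centroid distance in PC space
#'
#' The Euclidean distance between the mean retained-PC vectors of carriers
#' and non-carriers — the effect-size measure for a variant (or a gene's
#' combined carriers) on one module.
#'
#' @param phenotype a `module_phenotype`.
#' @param carriers logical vector flagging carrier individuals.
#' @return a one-row tibble: `module_id`, `n_carriers`, `n_noncarriers`,
#'   `centroid_distance`.
#' @export
effect_size_centroid <- function(phenotype, carriers) {
  stopifnot(inherits(phenotype, "module_phenotype"),
            length(carriers) == nrow(phenotype$scores))
  carriers <- as.logical(carriers)
  if (!any(carriers)) abort("carrier group is empty")
  if (all(carriers)) abort("non-carrier group is empty")
  mu1 <- colMeans(phenotype$scores[carriers, , drop = FALSE])
  mu0 <- colMeans(phenotype$scores[!carriers, , drop = FALSE])
  tibble(module_id = phenotype$segment_id,
         n_carriers = sum(carriers), n_noncarriers = sum(!carriers),
         centroid_distance = sqrt(sum((mu1 - mu0)^2)))
}
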