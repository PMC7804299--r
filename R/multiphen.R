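# Reverse-regression single-variant follow-up: genotype regressed on the
# module PCs jointly, likelihood-ratio tested against the intercept-only
# model. Robust for low-frequency variants where per-trait forward
# regressions are fragile.

#' Multivariate single-variant test (reverse ordinal regression)
#'
#' Regresses the genotype (as an ordered categorical dosage) on all K PCs of
#' a module jointly — i.e. finds the linear combination of PCs most
#' associated with the genotype — and reports the likelihood-ratio test
#' against the intercept-only model, `df = K`. With only two observed
#' genotype classes the proportional-odds model reduces to binary logistic
#' regression. When separation is detected (common with heterozygote-only
#' low-frequency variants), a Jeffreys-penalized (Firth-type) logistic fit
#' is used and flagged. Imputed fractional dosages are rounded to the
#' nearest integer category.
#'
#' @param dosage numeric vector of dosages (0/1/2, possibly fractional from
#'   imputation).
#' @param phenotype a `module_phenotype`.
#' @param variant_id optional identifier carried into the result.
#' @return a one-row tibble: `variant_id`, `module_id`, `p_value`, `df`,
#'   `model` (`"ordinal"`, `"logistic"` or `"firth"`), `carrier_count`.
#' @export
multiphen_test <- function(dosage, phenotype, variant_id = NA_character_) {
  stopifnot(inherits(phenotype, "module_phenotype"),
            length(dosage) == nrow(phenotype$scores))
  g <- round(dosage)
  if (length(unique(g)) < 2) abort("constant dosage cannot be tested")
  # the LRT is invariant to invertible linear maps of the PCs; standardize
  # so the optimizers see well-scaled columns (scores are in Procrustes
  # units, orders of magnitude below 1)
  S <- scale(phenotype$scores)
  K <- ncol(S)
  carriers <- sum(g >= 1)
  classes <- sort(unique(g))

  if (length(classes) >= 3) {
    fit <- tryCatch({
      y <- factor(g, levels = classes, ordered = TRUE)
      df_fit <- data.frame(y = y, S)
      full <- MASS::polr(y ~ ., data = df_fit, Hess = FALSE)
      nullm <- MASS::polr(y ~ 1, data = df_fit, Hess = FALSE)
      lrt <- nullm$deviance - full$deviance
      list(p = pchisq(lrt, df = K, lower.tail = FALSE), model = "ordinal")
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$p)) {
      return(tibble(variant_id = variant_id,
                    module_id = phenotype$segment_id,
                    p_value = fit$p, df = K, model = fit$model,
                    carrier_count = carriers))
    }
    # fall through: collapse to carrier / non-carrier
    g <- as.integer(g >= 1)
  } else {
    g <- as.integer(g == classes[2])
  }

  sep <- FALSE
  fit <- withCallingHandlers({
    full <- glm(g ~ S, family = binomial())
    nullm <- glm(g ~ 1, family = binomial())
    lrt <- nullm$deviance - full$deviance
    list(p = pchisq(lrt, df = K, lower.tail = FALSE), model = "logistic",
         maxcoef = max(abs(coef(full)[-1])))
  }, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      sep <<- TRUE
    invokeRestart("muffleWarning")
  })
  if (sep || fit$maxcoef > 15) {
    fr <- tryCatch(firth_lrt(g, S), error = function(e) NULL)
    if (is.null(fr)) {
      return(tibble(variant_id = variant_id,
                    module_id = phenotype$segment_id,
                    p_value = NA_real_, df = K, model = "separation",
                    carrier_count = carriers))
    }
    return(tibble(variant_id = variant_id, module_id = phenotype$segment_id,
                  p_value = fr, df = K, model = "firth",
                  carrier_count = carriers))
  }
  tibble(variant_id = variant_id, module_id = phenotype$segment_id,
         p_value = fit$p, df = K, model = fit$model,
         carrier_count = carriers)
}

# Firth-penalized logistic likelihood-ratio p-value for y ~ X vs y ~ 1
firth_lrt <- function(y, X) {
  l1 <- firth_logistic(cbind(1, X), y)
  l0 <- firth_logistic(matrix(1, length(y), 1), y)
  pchisq(max(0, 2 * (l1 - l0)), df = ncol(X), lower.tail = FALSE)
}

# penalized log-likelihood at the Firth (Jeffreys-prior) mode; Newton with
# step halving so the penalized likelihood increases monotonically even in
# ill-conditioned many-parameter, few-carrier fits
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  pen_ll <- function(b) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30)
    p <- stats::plogis(eta)
    I <- crossprod(X * sqrt(p * (1 - p)))
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  }
  b <- rep(0, ncol(X))
  ll <- pen_ll(b)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    Iinv <- tryCatch(solve(I), error = function(e) MASS::ginv(I))
    h <- rowSums((XW %*% Iinv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(Iinv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    for (half in 1:25) {
      cand <- b + step
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
    }
    b <- cand
    moved <- max(abs(step))
    ll <- ll_new
    if (moved < tol) break
  }
  ll
}

#' Single-variant follow-up of significant genes
#'
#' Every variant of a gene that passed the gene-level significance threshold
#' is tested with [multiphen_test()] against each module where the gene was
#' significant. No significant genes gives an empty (zero-row) table, not an
#' error.
#'
#' @param scan a `facemod_scan` tibble from [scan_genes()].
#' @param phenotypes the `module_phenotype_set` used in the scan.
#' @param genes the named list of `gene_variant_set`s used in the scan.
#' @param threshold gene-level significance threshold on `p_omnibus`.
#' @param best_only keep only each variant's best module (default `FALSE`,
#'   the full table).
#' @return a tibble sorted by `p_value`: `gene_id`, `variant_id`,
#'   `module_id`, `maf`, `p_value`, `df`, `model`, `carrier_count`.
#' @export
followup_scan <- function(scan, phenotypes, genes, threshold,
                          best_only = FALSE) {
  modules <- if (inherits(phenotypes, "module_phenotype_set")) {
    phenotypes$modules
  } else phenotypes
  hits <- dplyr::filter(as_tibble(scan), .data$p_omnibus < threshold)
  out <- list()
  for (i in seq_len(nrow(hits))) {
    g <- genes[[hits$gene_id[i]]]
    mod <- modules[[as.character(hits$module_id[i])]]
    dos <- impute_dosages(g$dosages, g$mafs)
    for (j in seq_along(g$variant_ids)) {
      if (var(dos[, j]) == 0) next
      r <- multiphen_test(dos[, j], mod, variant_id = g$variant_ids[j])
      r$gene_id <- g$gene_id
      r$maf <- g$mafs[j]
      out[[length(out) + 1]] <- r
    }
  }
  if (!length(out)) {
    return(tibble(gene_id = character(), variant_id = character(),
                  module_id = integer(), maf = numeric(),
                  p_value = numeric(), df = integer(), model = character(),
                  carrier_count = integer()))
  }
  res <- dplyr::arrange(
    dplyr::relocate(dplyr::bind_rows(out), "gene_id", "variant_id",
                    "module_id", "maf"),
    .data$p_value)
  if (best_only) {
    res <- dplyr::slice_min(dplyr::group_by(res, .data$variant_id),
                            .data$p_value, n = 1, with_ties = FALSE)
    res <- dplyr::arrange(dplyr::ungroup(res), .data$p_value)
  }
  res
}
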