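#' Test one gene against one module phenotype
#'
#' Computes the four kernel p-values (homogeneous/heterogeneous phenotype
#' kernel crossed with SKAT/burden genotype kernel) and the copula minP
#' omnibus for a single gene and a single module's null model. Missing
#' dosages are imputed to `2 * MAF`; variants monomorphic in the analysis
#' sample are dropped (message).
#'
#' @param null a `kernel_null_model` for the module.
#' @param gene a `gene_variant_set` (see [group_by_gene()]).
#' @param B omnibus resamples (default 500).
#' @param seed integer seed.
#' @return a one-row tibble: gene_id, m_variants, cum_mac, the four kernel
#'   p-values, `p_omnibus`, the four Q statistics, `method` flags.
#' @export
gene_kernel_test <- function(null, gene, B = 500, seed = 1L) {
  stopifnot(inherits(gene, "gene_variant_set"))
  dos <- impute_dosages(gene$dosages, gene$mafs)
  mono <- apply(dos, 2, function(v) var(v) == 0)
  if (any(mono)) {
    inform(sprintf("gene %s: dropping %d variant(s) monomorphic in sample",
                   gene$gene_id, sum(mono)))
    dos <- dos[, !mono, drop = FALSE]
  }
  w <- gene$weights[!mono]
  if (ncol(dos) == 0) {
    return(tibble(gene_id = gene$gene_id, m_variants = 0L,
                  cum_mac = 0, p_hom_skat = 1, p_het_skat = 1,
                  p_hom_burden = 1, p_het_burden = 1, p_omnibus = 1,
                  q_hom_skat = 0, q_het_skat = 0, q_hom_burden = 0,
                  q_het_burden = 0, method = "no_variance"))
  }
  gw <- sweep(dos, 2, w, `*`)
  gpg <- genotype_gram(null, gw)
  s <- score_matrix(null, gw)
  ps <- qs <- setNames(numeric(4), names(KERNELS))
  methods <- character(4)
  degenerate <- FALSE
  for (i in seq_along(KERNELS)) {
    kn <- names(KERNELS)[i]
    lam <- null_eigenvalues(null, gw, KERNELS[[i]][1], KERNELS[[i]][2],
                            gpg = gpg)
    qs[kn] <- q_statistic(s, KERNELS[[i]][1], KERNELS[[i]][2])
    if (!length(lam)) {
      ps[kn] <- 1; methods[i] <- "no_variance"; degenerate <- TRUE
    } else {
      pv <- pvalue_mixture_chisq(qs[kn], lam)
      ps[kn] <- pv$p
      methods[i] <- pv$method
    }
  }
  p_om <- if (degenerate) 1 else {
    omnibus_minp(ps, null, gw, B = B, seed = seed, gpg = gpg)$p_omnibus
  }
  tibble(gene_id = gene$gene_id,
         m_variants = ncol(dos), cum_mac = sum(dos),
         p_hom_skat = ps["hom_skat"], p_het_skat = ps["het_skat"],
         p_hom_burden = ps["hom_burden"], p_het_burden = ps["het_burden"],
         p_omnibus = p_om,
         q_hom_skat = qs["hom_skat"], q_het_skat = qs["het_skat"],
         q_hom_burden = qs["hom_burden"], q_het_burden = qs["het_burden"],
         method = paste(unique(methods), collapse = "+"))
}

#' Scan all genes against all module phenotypes
#'
#' Runs [gene_kernel_test()] for every (gene, module) pair: one null model
#' per module (intercept-only by default, since covariates are removed at
#' the phenotyping stage), four kernel p-values plus the copula omnibus per
#' pair. Individual identifiers must agree between phenotypes and genotypes;
#' a mismatch is an error before any computation. Deterministic under a
#' fixed seed (each pair draws from its own derived stream).
#'
#' @param phenotypes a `module_phenotype_set` (or named list of
#'   `module_phenotype`).
#' @param genes named list of `gene_variant_set`s.
#' @param geno_ids individual ids of the dosage rows.
#' @param B omnibus resamples per gene (default 500).
#' @param seed master seed.
#' @param covariates optional covariate matrix for the null models.
#' @return a `facemod_scan` tibble: one row per (gene, module) with the
#'   columns of [gene_kernel_test()] plus `module_id` and `n`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_individuals = 120, n_landmarks = 64, n_levels = 2,
#'                     n_genes = 4, maf_range = c(0.005, 0.01))
#' co <- simulate_cohort(cfg)
#' ph <- phenotype_modules(co$faces, co$covariates, n_levels = 2,
#'                         n_perm = 20, seed = 2)
#' gm <- group_by_gene(
#'   filter_variants(genotype_set_as_matrix(co$genotypes)),
#'   co$genotypes$gene_map)
#' head(scan_genes(ph, gm, geno_ids = rownames(co$genotypes$dosages),
#'                 B = 100, seed = 3))
#' }
#' @export
scan_genes <- function(phenotypes, genes, geno_ids, B = 500, seed = 1L,
                       covariates = NULL) {
  modules <- if (inherits(phenotypes, "module_phenotype_set")) {
    phenotypes$modules
  } else phenotypes
  if (!length(genes)) abort("no genes to test")
  for (m in modules) {
    if (!identical(m$ids, geno_ids)) {
      abort(paste0("individual ids of module ", m$segment_id,
                   " do not match the genotype rows"))
    }
  }
  rows <- vector("list", length(modules) * length(genes))
  k <- 0
  for (m in modules) {
    null <- fit_null(m$scores, covariates)
    for (g in genes) {
      k <- k + 1
      res <- gene_kernel_test(
        null, g, B = B,
        seed = stage_seed(seed, paste0("scan_", m$segment_id, "_",
                                       g$gene_id)))
      res$module_id <- m$segment_id
      res$n <- null$n
      rows[[k]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "gene_id", "module_id")
  class(out) <- c("facemod_scan", class(out))
  out
}

#' Convert a synthetic `genotype_set` into a `genotype_matrix`
#'
#' Adapter letting the in-memory generator output enter the filtering and
#' grouping path without a VCF round-trip (the VCF path is exercised by
#' [write_vcf()] + [read_genotypes()]).
#'
#' @param genotypes a `genotype_set` from [generate_genotypes()].
#' @return a `genotype_matrix` with observed MAF/MAC.
#' @export
genotype_set_as_matrix <- function(genotypes) {
  dos <- genotypes$dosages
  mac <- colSums(dos)
  flip <- mac > nrow(dos) # alt is the major allele in-sample
  dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  mac <- colSums(dos)
  structure(list(
    ids = rownames(dos), dosages = dos,
    variants = dplyr::mutate(genotypes$variants,
                             maf = mac / (2 * nrow(dos)), mac = mac,
                             n_missing = 0L, flipped = flip)),
    class = "genotype_matrix")
}
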