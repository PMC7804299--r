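# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small cohort with hierarchical covariance, used across modules
small_cohort <- function() {
  fixture("small_cohort", suppressMessages(simulate_cohort(
    synth_config(n_individuals = 150, n_landmarks = 64, n_levels = 3,
                 n_genes = 12, maf_range = c(0.005, 0.01), seed = 101))))
}

small_phenotypes <- function() {
  fixture("small_phenotypes", {
    co <- small_cohort()
    suppressMessages(phenotype_modules(co$faces, co$covariates,
                                       n_levels = 3, n_perm = 25,
                                       seed = 11))
  })
}

# internal helpers used directly by a few tests
subset_landmarks_for_test <- function(...) facemod:::subset_landmarks(...)
flatten_for_test <- function(...) facemod:::flatten_coords(...)

# desk-scale cohort (n = 500, L = 256, 5 levels) shared by the heavier
# property checks; generated once per run
desk_faces <- function() {
  fixture("desk_faces", generate_faces(synth_config(seed = 424)))
}

desk_hierarchy <- function() {
  fixture("desk_hierarchy",
          suppressMessages(build_hierarchy(desk_faces()$faces,
                                           n_levels = 5)))
}

# full-face module phenotype of the desk cohort with exactly 8 retained,
# covariate-adjusted PCs (the trait dimension used in the calibration runs)
desk_module8 <- function() {
  fixture("desk_module8", {
    cfg <- synth_config(seed = 424)
    gf <- desk_faces()
    gc <- generate_covariates(cfg, gf$faces, gf$truth)
    al <- gpa_align(gc$faces)$aligned
    ph <- suppressMessages(module_pca(al, segment_id = 1L))
    ph$scores <- ph$scores[, 1:8, drop = FALSE]
    ph$eigenvalues <- ph$eigenvalues[1:8]
    ph$loadings <- ph$loadings[, 1:8, drop = FALSE]
    pls_adjust(ph, gc$covariates)
  })
}

aligned_small <- function() {
  fixture("aligned_small", gpa_align(small_cohort()$faces)$aligned)
}

# a module phenotype with known iid-normal scores (for direct algebra tests)
toy_phenotype <- function(n = 200, k = 4, seed = 5) {
  set.seed(seed)
  structure(list(segment_id = 1L,
                 scores = matrix(rnorm(n * k), n, k),
                 eigenvalues = rep(1, k),
                 loadings = diag(k), center = rep(0, k),
                 ids = sprintf("id%04d", seq_len(n)), adjusted = TRUE),
            class = "module_phenotype")
}

# build a gene_variant_set directly from a dosage matrix
toy_gene <- function(dosages, gene_id = "G1") {
  maf <- colSums(dosages) / (2 * nrow(dosages))
  structure(list(gene_id = gene_id,
                 variant_ids = paste0("v", seq_len(ncol(dosages))),
                 dosages = dosages, mafs = maf,
                 weights = variant_weights(maf)),
            class = "gene_variant_set")
}

# random rare-variant dosage matrix that passes the default filters
rare_dosages <- function(n, m, maf = c(0.005, 0.01), min_mac = 4) {
  repeat {
    mafs <- runif(m, maf[1], maf[2])
    dos <- matrix(rbinom(n * m, 2, rep(mafs, each = n)), n, m)
    if (all(colSums(dos) >= min_mac)) return(dos)
  }
}
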