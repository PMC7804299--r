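# Synthetic cohort generator: degenerate cases, closed-form moments,
# determinism, and effect planting.

quiet_cfg <- function(...) synth_config(...)

test_that("zero variance and identity transforms reproduce the template", {
  cfg <- quiet_cfg(n_individuals = 10, n_landmarks = 64, n_levels = 3,
                   deform_sd = 0, noise_sd = 0, max_rotation_deg = 0,
                   translate_sd = 0, scale_range = c(1, 1), seed = 1)
  gf <- generate_faces(cfg)
  tmpl <- gf$truth$template$coords
  for (i in 1:10) {
    expect_equal(gf$faces$coords[i, , ], tmpl, ignore_attr = TRUE)
  }
})

test_that("noise-only landmark displacements have covariance sigma^2 I", {
  sigma <- 0.5
  cfg <- quiet_cfg(n_individuals = 2000, n_landmarks = 16, n_levels = 1,
                   deform_sd = 0, noise_sd = sigma, max_rotation_deg = 0,
                   translate_sd = 0, scale_range = c(1, 1), seed = 2)
  gf <- generate_faces(cfg)
  disp <- gf$faces$coords[, 5, ] # one landmark's n x 3 displacements
  disp <- sweep(disp, 2, colMeans(disp))
  S <- crossprod(disp) / (nrow(disp) - 1)
  # Monte-Carlo error on a variance at n = 2000 is about sigma^2*sqrt(2/n)
  expect_lt(max(abs(diag(S) - sigma^2)), 4 * sigma^2 * sqrt(2 / 2000))
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 4 * sigma^2 / sqrt(2000))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- quiet_cfg(n_individuals = 20, n_landmarks = 64, n_levels = 3,
                   n_genes = 4, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$faces$coords, b$faces$coords)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$covariates, b$covariates)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(a$genotypes, f1); write_vcf(b$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("too few landmarks for the requested hierarchy is rejected", {
  expect_error(synth_config(n_landmarks = 16, n_levels = 5),
               "cannot host")
  expect_error(synth_config(maf_range = c(0.05, 0.2)), "low-frequency")
})

test_that("ground-truth hierarchy is a proper nested partition", {
  cfg <- quiet_cfg(n_individuals = 5, n_landmarks = 256, n_levels = 5)
  gf <- generate_faces(cfg)
  segs <- gf$truth$segments
  expect_length(segs, 31)
  ids <- vapply(segs, `[[`, 1L, "segment_id")
  for (s in segs) {
    if (s$segment_id * 2 + 1 <= 31) {
      kids <- c(segs[[match(2 * s$segment_id, ids)]]$landmarks,
                segs[[match(2 * s$segment_id + 1, ids)]]$landmarks)
      expect_setequal(kids, s$landmarks)
      expect_length(kids, length(s$landmarks)) # disjoint children
    }
  }
  expect_true(all(gf$truth$leaf_assignment > 0))
  # rotations are proper
  dets <- vapply(gf$truth$rotations, det, numeric(1))
  expect_equal(dets, rep(1, 5), tolerance = 1e-10)
})

test_that("dosage MAC matches the binomial expectation", {
  cfg <- quiet_cfg(n_individuals = 2000, n_landmarks = 64, n_levels = 3,
                   n_genes = 60, variants_per_gene = c(5, 5),
                   maf_range = c(0.005, 0.005), seed = 3)
  g <- generate_genotypes(cfg)
  macs <- colSums(g$dosages)
  # E[MAC] = 2 n MAF = 20; SE of the mean over 300 variants
  expect_lt(abs(mean(macs) - 20), 4 * sqrt(20 / 300))
})

test_that("common variants are all removed by the low-frequency filter", {
  cfg <- quiet_cfg(n_individuals = 200, n_landmarks = 64, n_levels = 3,
                   n_genes = 5, maf_range = c(0.4, 0.5), common_mode = TRUE,
                   seed = 4)
  g <- genotype_set_as_matrix(generate_genotypes(cfg))
  expect_error(filter_variants(g, maf_max = 0.01), "no variant passes")
})

test_that("planted gene effects displace exactly the carriers' segment", {
  cfg <- quiet_cfg(n_individuals = 50, n_landmarks = 64, n_levels = 3,
                   n_genes = 3, maf_range = c(0.005, 0.01),
                   deform_sd = 0, noise_sd = 0, max_rotation_deg = 0,
                   translate_sd = 0, scale_range = c(1, 1), seed = 8)
  gf <- generate_faces(cfg)
  geno <- generate_genotypes(cfg, ids = gf$faces$ids)
  vids <- geno$gene_map$variant_id[geno$gene_map$gene_id == "G0001"]
  carriers <- rowSums(geno$dosages[, vids, drop = FALSE]) >= 1
  expect_true(any(carriers)) # seed chosen so carriers exist
  seg <- gf$truth$segments[[5]]$landmarks

  eff0 <- list(gene_id = "G0001", segment_id = 5, magnitude = 0)
  expect_identical(
    plant_gene_effect(gf$faces, geno, eff0, gf$truth)$coords,
    gf$faces$coords)

  d <- 2.5
  eff <- list(gene_id = "G0001", segment_id = 5, magnitude = d)
  planted <- plant_gene_effect(gf$faces, geno, eff, gf$truth)
  i <- which(carriers)[1]
  delta <- planted$coords[i, , ] - gf$faces$coords[i, , ]
  expect_equal(sqrt(sum(delta^2)), d, tolerance = 1e-10)
  expect_equal(delta[-seg, ], matrix(0, 64 - length(seg), 3),
               ignore_attr = TRUE)
  j <- which(!carriers)[1]
  expect_equal(planted$coords[j, , ], gf$faces$coords[j, , ])
})

test_that("planting warns and leaves faces unchanged without carriers", {
  cfg <- quiet_cfg(n_individuals = 20, n_landmarks = 64, n_levels = 3,
                   n_genes = 2, maf_range = c(1e-5, 2e-5), seed = 9)
  gf <- generate_faces(cfg)
  geno <- generate_genotypes(cfg, ids = gf$faces$ids)
  expect_true(all(geno$dosages[, geno$gene_map$gene_id == "G0001"] == 0))
  expect_warning(
    out <- plant_gene_effect(gf$faces, geno,
                             list(gene_id = "G0001", segment_id = 2,
                                  magnitude = 1), gf$truth),
    "no carriers")
  expect_identical(out$coords, gf$faces$coords)
})

test_that("covariate table has the declared structure and planted effects", {
  co <- small_cohort()
  expect_equal(nrow(co$covariates), 150)
  expect_true(all(c("id", "sex", "age", "height", "weight", "size",
                    "ancestry_pc1") %in% names(co$covariates)))
  expect_true(all(co$covariates$sex %in% 0:1))

  # planted sex effect: centroid separation of the full-face phenotype
  # along sex must be positive
  raw <- suppressMessages(module_pca(
    gpa_align(co$faces)$aligned, segment_id = 1L))
  es <- effect_size_centroid(raw, co$covariates$sex == 1)
  expect_gt(es$centroid_distance, 0)
})

test_that("zero covariate effects leave shape independent of covariates", {
  cfg <- quiet_cfg(n_individuals = 300, n_landmarks = 16, n_levels = 1,
                   covariate_effects = c(sex = 0, age = 0, height = 0,
                                         weight = 0, ancestry = 0),
                   max_rotation_deg = 0, translate_sd = 0,
                   scale_range = c(1, 1), seed = 12)
  gf <- generate_faces(cfg)
  gc <- generate_covariates(cfg, gf$faces, gf$truth)
  ph <- suppressMessages(module_pca(gpa_align(gc$faces)$aligned))
  r2 <- summary(lm(ph$scores[, 1] ~ sex + age + height + weight,
                   data = gc$covariates))$r.squared
  expect_lt(r2, 0.05)
})
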