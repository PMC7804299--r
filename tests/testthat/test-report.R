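# Multiplicity correction, effect sizes, morphs, report assembly.

test_that("Li-Ji effective tests match the exact reference cases", {
  expect_equal(as.numeric(effective_tests_li_ji(diag(31))), 31)
  ones <- matrix(1, 31, 31)
  expect_equal(as.numeric(effective_tests_li_ji(ones)), 1)
  blk <- kronecker(diag(5), matrix(1, 3, 3))
  expect_equal(as.numeric(effective_tests_li_ji(blk)), 5)
  expect_error(effective_tests_li_ji(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("M_eff decreases with equicorrelation strength", {
  meffs <- vapply(seq(0, 0.9, by = 0.15), function(rho) {
    m <- matrix(rho, 10, 10); diag(m) <- 1
    as.numeric(effective_tests_li_ji(m))
  }, numeric(1))
  expect_true(all(diff(meffs) <= 1e-10))
  expect_true(all(meffs >= 1 & meffs <= 10))
})

test_that("the significance threshold follows the Bonferroni arithmetic", {
  expect_equal(signif(significance_threshold(8091, 19, 0.05), 2), 3.3e-7)
  expect_equal(significance_threshold(1, 1, 0.05), 0.05)
  expect_equal(significance_threshold(100, 10, 0.05), 5e-5)
})

test_that("module self-similarity is 1 and disjoint noise modules near 0", {
  set.seed(1)
  mods <- list(a = toy_phenotype(400, 3, seed = 2),
               b = toy_phenotype(400, 4, seed = 3))
  rv <- module_correlation(mods)
  expect_equal(diag(rv), c(1, 1), ignore_attr = TRUE)
  expect_lt(rv[1, 2], 0.05)
})

test_that("nested modules built from shared landmarks correlate strongly", {
  ph <- small_phenotypes()
  rv <- module_correlation(ph)
  # child (id 2) shares all its landmarks with the full face (id 1)
  expect_gt(rv["2", "1"], 0.5)
  plan <- multiplicity_plan(ph, n_genes = 12)
  expect_gte(plan$m_eff, 1)
  expect_lte(plan$m_eff, 7)
  expect_equal(plan$threshold,
               0.05 / (12 * plan$m_eff), tolerance = 1e-15)
})

test_that("centroid effect size measures a planted shift and isometries", {
  set.seed(4)
  ph <- toy_phenotype(500, 4)
  carriers <- rep(c(TRUE, FALSE), c(50, 450))
  # identical group means: distance 0
  ph0 <- ph
  ph0$scores <- matrix(rep(colMeans(ph$scores), each = 500), 500, 4)
  expect_equal(effect_size_centroid(ph0, carriers)$centroid_distance, 0)
  # planted shift v recovered as noise vanishes
  v <- c(2, -1, 0.5, 1)
  ph1 <- ph
  ph1$scores[carriers, ] <- sweep(ph1$scores[carriers, ], 2, -v)
  d <- effect_size_centroid(ph1, carriers)$centroid_distance
  expect_equal(d, sqrt(sum(v^2)), tolerance = 0.35)
  # orthogonal rotation of the PC basis preserves the distance
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  ph2 <- ph1
  ph2$scores <- ph1$scores %*% Q
  expect_equal(effect_size_centroid(ph2, carriers)$centroid_distance, d,
               tolerance = 1e-10)
  expect_error(effect_size_centroid(ph, rep(FALSE, 500)), "empty")
})

test_that("morphs are local, linear in exaggeration, and zero when equal", {
  co <- small_cohort()
  h <- small_phenotypes()$hierarchy
  set.seed(5)
  carriers <- seq_len(150) <= 20
  m1 <- morph_export(co$faces, h, 4, carriers, exaggeration = 1)
  m7 <- morph_export(co$faces, h, 4, carriers, exaggeration = 7)
  expect_equal(nrow(m1), length(segment_landmarks(h, 4)))
  expect_equal(m7$dx, 7 * m1$dx, tolerance = 1e-10)
  expect_equal(m7$normal_disp, 7 * m1$normal_disp, tolerance = 1e-10)
  expect_error(morph_export(co$faces, h, 99, carriers), "unknown")

  # carriers whose shapes duplicate the non-carriers: zero displacement
  dup <- co$faces
  dup$coords[1:75, , ] <- dup$coords[76:150, , ]
  mz <- morph_export(dup, h, 4, seq_len(150) <= 75)
  expect_lt(max(abs(c(mz$dx, mz$dy, mz$dz))), 1e-10)

  ply <- tempfile(fileext = ".ply")
  write_morph_ply(m7, ply)
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("end_header", lines)), 1)
  expect_equal(length(lines) - which(lines == "end_header"), nrow(m7))
})

test_that("report assembly: cardinality, empty case, manifest round trip", {
  ph <- small_phenotypes()
  set.seed(6)
  genes <- paste0("G", 1:5)
  scan <- tidyr::expand_grid(gene_id = genes,
                             module_id = ph$hierarchy$segment_id)
  scan$p_omnibus <- runif(nrow(scan), 0.2, 1)
  scan$p_omnibus[scan$gene_id == "G3" & scan$module_id == 5] <- 1e-10
  plan <- multiplicity_plan(ph, n_genes = 5)
  rep1 <- assemble_report(scan, plan)
  expect_equal(nrow(rep1$significant), 1)
  expect_equal(rep1$significant$gene_id, "G3")
  expect_equal(nrow(rep1$manhattan), 35)
  expect_equal(unname(table(rep1$manhattan$gene_id)), rep(7L, 5),
               ignore_attr = TRUE)

  scan2 <- scan
  scan2$p_omnibus <- pmax(scan2$p_omnibus, 0.2)
  rep2 <- assemble_report(scan2, plan)
  expect_equal(nrow(rep2$significant), 0)

  d <- tempfile()
  write_report(rep1, d, seed = 99)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$m_eff, plan$m_eff)
  expect_equal(man$seed, 99)
  expect_true(file.exists(file.path(d, "significant_genes.tsv")))
})
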