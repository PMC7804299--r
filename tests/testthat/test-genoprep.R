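# VCF reading, minor-allele orientation, filtering, gene grouping, weights.

toy_matrix <- function(dosages, mafs = NULL, macs = NULL) {
  n <- nrow(dosages); M <- ncol(dosages)
  if (is.null(macs)) macs <- colSums(dosages, na.rm = TRUE)
  if (is.null(mafs)) mafs <- macs / (2 * n)
  structure(list(
    ids = sprintf("s%02d", seq_len(n)), dosages = dosages,
    variants = tibble::tibble(
      variant_id = paste0("v", seq_len(M)), chrom = "1",
      pos = seq_len(M) * 100L, ref = "A", alt = "G",
      maf = mafs, mac = macs, n_missing = colSums(is.na(dosages)),
      flipped = FALSE)), class = "genotype_matrix")
}

test_that("generated VCF round-trips losslessly through the reader", {
  co <- small_cohort()
  f <- tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, f)
  g <- read_genotypes(f)
  expect_identical(g$ids, rownames(co$genotypes$dosages))
  # MAF < 0.5 everywhere, so no site is re-oriented
  expect_equal(unname(g$dosages), unname(co$genotypes$dosages))
  expect_equal(g$variants$variant_id, co$genotypes$variants$variant_id)
})

test_that("a common ALT allele is re-oriented to the minor allele", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:5)), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "1/1", "1/1", "1/1", "0/1", "0/0"), collapse = "\t")), f)
  g <- read_genotypes(f)
  # ALT frequency 7/10: dosages flipped, MAF = 0.3
  expect_equal(g$variants$maf, 0.3)
  expect_true(g$variants$flipped)
  expect_equal(unname(g$dosages[, 1]), c(0, 0, 0, 1, 2))
})

test_that("missing genotypes leave the MAF denominator", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:6)), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "./.", "0/0", "0/1", "./.", "0/0"), collapse = "\t")), f)
  g <- read_genotypes(f)
  # 2 of 6 missing: MAC = 2, MAF = 2 / (2 * 4) = 0.25 (hand-computed)
  expect_equal(g$variants$mac, 2)
  expect_equal(g$variants$maf, 0.25)
  expect_equal(g$variants$n_missing, 2)
  expect_true(is.na(g$dosages[2, 1]))
})

test_that("a requested sample missing from the VCF is an error", {
  co <- small_cohort()
  f <- tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, f)
  expect_error(read_genotypes(f, samples = c("id0001", "ghost")), "ghost")
  sub <- read_genotypes(f, samples = c("id0003", "id0001"))
  expect_identical(sub$ids, c("id0003", "id0001"))
})

test_that("MAC and MAF filters use the stated boundaries", {
  n <- 2000
  dos <- matrix(0, n, 4)
  for (j in 1:4) dos[seq_len(c(1, 3, 4, 10)[j]), j] <- 1
  g <- toy_matrix(dos)
  kept <- suppressMessages(filter_variants(g))
  expect_setequal(kept$variants$variant_id, c("v3", "v4"))
  log <- attr(kept, "filter_log")
  expect_equal(sum(log$kept), 2)

  # MAF exactly at the bound is removed (strict inequality)
  dos2 <- cbind(c(rep(1, 20), rep(0, 980)), c(rep(1, 4), rep(0, 996)))
  g2 <- toy_matrix(dos2) # MAFs 0.01 and 0.002
  kept2 <- filter_variants(g2, maf_max = 0.01, mac_min = 2)
  expect_equal(kept2$variants$variant_id, "v2")
})

test_that("filtering is order-independent", {
  set.seed(1)
  dos <- matrix(rbinom(500 * 30, 2, 0.004), 500, 30)
  g <- toy_matrix(dos)
  a <- filter_variants(g, maf_max = 0.01, mac_min = 4)
  # apply the rules one at a time in both orders
  maf_first <- g$variants$variant_id[g$variants$maf < 0.01]
  both1 <- intersect(maf_first,
                     g$variants$variant_id[g$variants$mac >= 4])
  mac_first <- g$variants$variant_id[g$variants$mac >= 4]
  both2 <- intersect(mac_first,
                     g$variants$variant_id[g$variants$maf < 0.01])
  expect_setequal(both1, both2)
  expect_setequal(a$variants$variant_id, both1)
})

test_that("gene grouping enforces the minimum and duplicates shared variants", {
  set.seed(2)
  dos <- matrix(rbinom(100 * 9, 2, 0.2), 100, 9)
  g <- toy_matrix(dos)
  map <- tibble::tibble(
    variant_id = c(paste0("v", 1:9), "v1"),
    gene_id = c("A", "A", "B", "B", "C", "C", "C", "C", "C", "D"))
  sets <- suppressMessages(group_by_gene(g, map, min_variants = 2))
  expect_setequal(names(sets), c("A", "B", "C")) # D has 1 variant: dropped
  expect_equal(vapply(sets, function(s) length(s$variant_ids), integer(1)),
               c(A = 2L, B = 2L, C = 5L))
  # deterministic (chrom, pos) ordering inside genes
  expect_equal(sets$C$variant_ids, paste0("v", 5:9))
  # v1 contributes to both A and (if mapped) D
  expect_true("v1" %in% sets$A$variant_ids)
})

test_that("variant weights follow the Beta density", {
  expect_gt(variant_weights(0.001), variant_weights(0.009))
  expect_equal(variant_weights(c(0.1, 0.4), 1, 1), c(1, 1))
  expect_equal(variant_weights(0.005), 25 * (1 - 0.005)^24,
               tolerance = 1e-12)
  expect_error(variant_weights(c(0.01, 0)), "monomorphic")
})
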