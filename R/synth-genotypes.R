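#' Generate exome-style low-frequency genotypes grouped into genes
#'
#' Per gene, a number of variants drawn from `config$variants_per_gene`;
#' per variant, a true minor-allele frequency drawn uniformly from
#' `config$maf_range` and dosages sampled as Binomial(2, MAF) independently
#' across unrelated individuals. Genes are laid out on chromosomes 1..22 in
#' round-robin order with increasing positions (hg19-style coordinates are
#' nominal). The object round-trips losslessly through [write_vcf()] and
#' [read_genotypes()].
#'
#' @param config a [synth_config()].
#' @param ids individual identifiers (defaults to `id0001...`).
#' @return an object of class `genotype_set`: list with `dosages`
#'   (n x M integer matrix, minor-allele counts, column names = variant ids),
#'   `variants` (tibble: variant_id, chrom, pos, ref, alt, maf_true) and
#'   `gene_map` (tibble: variant_id, gene_id).
#' @examples
#' cfg <- synth_config(n_individuals = 100, n_landmarks = 64, n_levels = 3,
#'                     n_genes = 5)
#' g <- generate_genotypes(cfg)
#' dim(g$dosages)
#' @export
generate_genotypes <- function(config, ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_individuals
  if (is.null(ids)) ids <- sprintf("id%04d", seq_len(n))
  with_seed(stage_seed(config$seed, "genotypes"), {
    vr <- config$variants_per_gene
    m_per_gene <- if (vr[1] == vr[2]) rep(vr[1], config$n_genes) else
      sample(vr[1]:vr[2], config$n_genes, replace = TRUE)
    M <- sum(m_per_gene)
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    gene_of <- rep(gene_ids, times = m_per_gene)
    gene_index <- rep(seq_len(config$n_genes), times = m_per_gene)
    within <- unlist(lapply(m_per_gene, seq_len))
    chrom <- ((gene_index - 1) %% 22) + 1
    pos <- 1e6 + ((gene_index - 1) %/% 22) * 1e5 + within * 100
    variant_id <- sprintf("v%05d", seq_len(M))
    maf <- runif(M, config$maf_range[1], config$maf_range[2])
    dos <- matrix(rbinom(n * M, 2, rep(maf, each = n)), n, M,
                  dimnames = list(ids, variant_id))
    structure(list(
      dosages = dos,
      variants = tibble(variant_id = variant_id,
                        chrom = as.integer(chrom), pos = as.integer(pos),
                        ref = "A", alt = "G", maf_true = maf),
      gene_map = tibble(variant_id = variant_id, gene_id = gene_of)),
      class = "genotype_set", seed = config$seed)
  })
}

#' Write a genotype set as a VCF 4.2 file with GT fields
#'
#' Plain-text, uncompressed; dosage 0/1/2 encoded as `0/0`, `0/1`, `1/1`
#' with the minor allele as ALT. `NA` dosages become `./.`.
#'
#' @param genotypes a `genotype_set` (or any list with `dosages`,`variants`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  dos <- genotypes$dosages
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=facemod_synthetic_cohort",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  gt <- matrix(gt_code[as.character(t(dos))], nrow = ncol(dos))
  gt[is.na(gt)] <- "./."
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a variant-to-gene map as a two-column TSV
#' @param genotypes a `genotype_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(genotypes, path) {
  write.table(genotypes$gene_map, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the generators: faces with hierarchical shape covariance,
#' covariates with planted linear effects, genotypes, and planted
#' gene-by-segment effects. Each stage draws from its own seed stream derived
#' from `config$seed`, so the whole cohort is reproducible bit-for-bit.
#'
#' @param config a [synth_config()].
#' @return list with `faces` (landmark_set), `covariates` (tibble),
#'   `genotypes` (genotype_set) and `truth` (face_ground_truth, with
#'   `causal_genes` filled in).
#' @examples
#' cohort <- simulate_cohort(synth_config(n_individuals = 40,
#'                                        n_landmarks = 64, n_levels = 3,
#'                                        n_genes = 10))
#' names(cohort)
#' @export
simulate_cohort <- function(config) {
  gf <- generate_faces(config)
  gc <- generate_covariates(config, gf$faces, gf$truth)
  geno <- generate_genotypes(config, ids = gf$faces$ids)
  faces <- gc$faces
  for (pe in config$planted_effects) {
    faces <- plant_gene_effect(faces, geno, pe, gf$truth)
  }
  gf$truth$causal_genes <-
    unique(vapply(config$planted_effects, `[[`, "", "gene_id"))
  list(faces = faces, covariates = gc$covariates, genotypes = geno,
       truth = gf$truth)
}
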