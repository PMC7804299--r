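#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end: cohort simulation, phenotyping
#' (hierarchy, per-module PCA with parallel-analysis retention, covariate
#' residualization), genotype filtering and gene grouping, the gene-by-module
#' kernel scan with omnibus, single-variant follow-up of significant genes,
#' and report assembly with Li-Ji multiplicity correction. Every stage draws
#' from a seed stream derived from `config$seed`, so reruns are
#' reproducible; when `out_dir` is given all artifacts (landmark TSV, VCF,
#' gene map, covariates, phenotype TSVs, hierarchy JSON, scan and follow-up
#' tables, report bundle) are written there.
#'
#' @param config a [synth_config()] describing the cohort.
#' @param out_dir optional output directory for artifacts.
#' @param n_levels hierarchy depth (default `config$n_levels`).
#' @param n_perm parallel-analysis permutations (default 100).
#' @param maf_max,mac_min variant filters (defaults 0.01 and 4).
#' @param B omnibus resamples per gene (default 500).
#' @param alpha family-wise level for the significance threshold.
#' @param hierarchy optional frozen `segment_hierarchy` to reuse instead of
#'   re-estimating segment boundaries from this cohort.
#' @return a list with `cohort`, `phenotypes`, `genes`, `scan`, `plan`,
#'   `followup`, `report`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_individuals = 120, n_landmarks = 64, n_levels = 2,
#'                     n_genes = 5, seed = 11)
#' res <- run_pipeline(cfg, n_perm = 20, B = 100)
#' res$report
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         n_levels = config$n_levels, n_perm = 100,
                         maf_max = 0.01, mac_min = 4, B = 500,
                         alpha = 0.05, hierarchy = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cohort <- simulate_cohort(config)

  phen <- phenotype_modules(cohort$faces, cohort$covariates,
                            hierarchy = hierarchy, n_levels = n_levels,
                            n_perm = n_perm,
                            seed = stage_seed(config$seed, "phenotype"))

  gmat <- genotype_set_as_matrix(cohort$genotypes)
  filt <- filter_variants(gmat, maf_max = maf_max, mac_min = mac_min)
  genes <- group_by_gene(filt, cohort$genotypes$gene_map)
  if (!length(genes)) abort("no genes with enough qualified variants")

  scan <- scan_genes(phen, genes, geno_ids = gmat$ids, B = B,
                     seed = stage_seed(config$seed, "scan"))

  plan <- multiplicity_plan(phen, n_genes = length(genes), alpha = alpha)
  followup <- followup_scan(scan, phen, genes, threshold = plan$threshold)

  sig <- dplyr::filter(scan, .data$p_omnibus < plan$threshold)
  # effect size in each significant gene's best (smallest-p) module
  best <- if (nrow(sig)) {
    dplyr::ungroup(dplyr::slice_min(dplyr::group_by(sig, .data$gene_id),
                                    .data$p_omnibus, n = 1,
                                    with_ties = FALSE))
  } else sig
  effects <- if (nrow(best)) {
    dplyr::bind_rows(lapply(seq_len(nrow(best)), function(i) {
      g <- genes[[best$gene_id[i]]]
      carriers <- rowSums(impute_dosages(g$dosages, g$mafs) >= 0.5) > 0
      es <- effect_size_centroid(
        phen$modules[[as.character(best$module_id[i])]], carriers)
      es$gene_id <- best$gene_id[i]
      es
    }))
  } else NULL
  report <- assemble_report(scan, plan, effects = effects)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_landmarks(cohort$faces, file.path(out_dir, "landmarks.tsv"))
    write.table(cohort$covariates, file.path(out_dir, "covariates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf"))
    write_gene_map(cohort$genotypes, file.path(out_dir, "gene_map.tsv"))
    write_hierarchy(phen$hierarchy, file.path(out_dir, "hierarchy.json"))
    write_phenotypes(phen, file.path(out_dir, "phenotypes"))
    write.table(scan, file.path(out_dir, "scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(followup, file.path(out_dir, "followup.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_report(report, file.path(out_dir, "report"), seed = config$seed)
  }

  list(cohort = cohort, phenotypes = phen, genes = genes, scan = scan,
       plan = plan, followup = followup, report = report)
}
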