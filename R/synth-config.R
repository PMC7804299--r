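#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()] and its
#' component generators. The generator emulates the data structure the
#' downstream analysis assumes: a cohort of unrelated individuals with dense
#' homologous facial landmarks whose covariance is organised along a binary
#' hierarchy of co-varying landmark groups, standard demographic covariates
#' with linear shape effects, and exome-style low-frequency genotypes grouped
#' into genes, optionally with planted gene effects confined to one segment.
#'
#' Landmarks live on a regular \eqn{g \times g} grid (so `n_landmarks` must be
#' a perfect square) embedded as a curved 3D patch at millimetre scale. The
#' ground-truth segment hierarchy is obtained by recursively halving the grid
#' (alternating axes), giving `2^n_levels - 1` segments; every tree node
#' contributes a low-rank deformation field confined to its landmarks, so
#' landmarks within a segment co-vary more strongly than landmarks across
#' segments.
#'
#' @param n_individuals number of individuals.
#' @param n_landmarks number of quasi-landmarks (perfect square).
#' @param n_levels depth of the binary segment hierarchy (default 5, giving
#'   31 segments).
#' @param deform_sd per-level standard deviation (mm) of the deformation-field
#'   coefficients, length `n_levels` (recycled if scalar). The default is a
#'   geometrically decaying profile `1.6 * 0.85^level`, stronger globally
#'   than locally.
#' @param deform_rank number of deformation basis fields per tree node.
#' @param noise_sd iid landmark noise standard deviation (mm).
#' @param covariate_effects named numeric vector of shape-effect magnitudes
#'   (mm displacement per SD of the covariate) for `sex`, `age`, `height`,
#'   `weight` and ancestry PCs (`ancestry` applies to every PC).
#' @param n_ancestry_pcs number of ancestry principal components.
#' @param n_genes number of genes.
#' @param variants_per_gene integer range `c(lo, hi)` of variants per gene.
#' @param maf_range allele-frequency range `(low, high]`; must lie within
#'   `(0, 0.01]` unless `common_mode = TRUE`.
#' @param common_mode allow MAFs above 1% (for negative-control fixtures).
#' @param planted_effects list of planted gene effects, each a list with
#'   `gene_id`, `segment_id`, `magnitude` (mm, pre-noise displacement norm).
#' @param max_rotation_deg,translate_sd,scale_range per-individual random
#'   rigid perturbation: rotation angle bound (degrees), translation SD (mm),
#'   and uniform scale range. Set to `0, 0, c(1, 1)` for identity transforms.
#' @param seed integer seed; every generator call derives its own stream.
#'
#' @return an object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_individuals = 50, n_landmarks = 64, n_levels = 3)
#' @export
synth_config <- function(n_individuals = 500,
                         n_landmarks = 256,
                         n_levels = 5,
                         deform_sd = NULL,
                         deform_rank = 2,
                         noise_sd = 0.2,
                         covariate_effects = c(sex = 0.5, age = 0.3,
                                               height = 0.2, weight = 0.2,
                                               ancestry = 0.1),
                         n_ancestry_pcs = 4,
                         n_genes = 200,
                         variants_per_gene = c(5, 5),
                         maf_range = c(0.001, 0.01),
                         common_mode = FALSE,
                         planted_effects = list(),
                         max_rotation_deg = 15,
                         translate_sd = 5,
                         scale_range = c(0.9, 1.1),
                         seed = 1L) {
  stopifnot(n_individuals >= 2, n_levels >= 1, deform_rank >= 1,
            noise_sd >= 0, n_genes >= 0, length(variants_per_gene) == 2,
            variants_per_gene[1] >= 1,
            variants_per_gene[1] <= variants_per_gene[2],
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] <= maf_range[2],
            length(scale_range) == 2, scale_range[1] <= scale_range[2])
  g <- sqrt(n_landmarks)
  if (g != round(g)) {
    abort("`n_landmarks` must be a perfect square (landmarks form a grid).")
  }
  n_leaves <- 2^(n_levels - 1)
  if (n_landmarks < 4 * n_leaves) {
    abort(sprintf(paste0(
      "n_landmarks = %d cannot host the %d leaf segments of a %d-level ",
      "hierarchy (need at least 4 landmarks per leaf, i.e. %d landmarks)."),
      n_landmarks, n_leaves, n_levels, 4 * n_leaves))
  }
  if (!common_mode && maf_range[2] > 0.01) {
    abort("`maf_range` must lie within (0, 0.01] in low-frequency mode.")
  }
  if (is.null(deform_sd)) deform_sd <- 1.6 * 0.85^(seq_len(n_levels) - 1)
  if (length(deform_sd) == 1) deform_sd <- rep(deform_sd, n_levels)
  if (length(deform_sd) != n_levels) {
    abort("`deform_sd` must have length 1 or `n_levels`.")
  }
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_landmarks = as.integer(n_landmarks),
    n_levels = as.integer(n_levels),
    deform_sd = deform_sd, deform_rank = as.integer(deform_rank),
    noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    n_ancestry_pcs = as.integer(n_ancestry_pcs),
    n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    maf_range = maf_range, common_mode = common_mode,
    planted_effects = planted_effects,
    max_rotation_deg = max_rotation_deg, translate_sd = translate_sd,
    scale_range = scale_range,
    seed = as.integer(seed)), class = "synth_config")
  # planted segment ids must exist in the template hierarchy
  n_seg <- 2^n_levels - 1
  for (pe in planted_effects) {
    stopifnot(!is.null(pe$gene_id), !is.null(pe$segment_id),
              !is.null(pe$magnitude))
    if (pe$segment_id < 1 || pe$segment_id > n_seg) {
      abort(sprintf("planted segment_id %s outside the hierarchy (1..%d)",
                    pe$segment_id, n_seg))
    }
  }
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d individuals, %d landmarks, %d-level hierarchy (%d segments)\n",
              x$n_individuals, x$n_landmarks, x$n_levels, 2^x$n_levels - 1))
  cat(sprintf("  %d genes, %d-%d variants/gene, MAF in (%g, %g]\n",
              x$n_genes, x$variants_per_gene[1], x$variants_per_gene[2],
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  %d planted gene effect(s); seed %d\n",
              length(x$planted_effects), x$seed))
  invisible(x)
}
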