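#' Read genotypes from a VCF into a dosage matrix
#'
#' Parses GT fields (via vcfR), converts to allele dosages and orients every
#' site to its minor allele, so dosage counts minor alleles and
#' `MAF = MAC / (2 * n_nonmissing)` is in `[0, 0.5]`. Multi-allelic sites
#' are skipped with a message (the generator never writes them). Missing
#' genotypes (`./.`) stay `NA` and are excluded from the MAF denominator.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional sample subset / ordering; an error lists any
#'   requested sample absent from the file.
#' @return a `genotype_matrix`: list with `ids`, `dosages` (n x M, minor
#'   allele counts with `NA` for missing), and `variants` tibble
#'   (`variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `mac`,
#'   `n_missing`, `flipped`).
#' @export
read_genotypes <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    inform(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- colnames(gt)
  if (!is.null(samples)) {
    missing <- setdiff(samples, ids)
    if (length(missing)) {
      abort(paste0("samples absent from VCF: ",
                   paste(head(missing, 10), collapse = ", ")))
    }
    gt <- gt[, samples, drop = FALSE]
    ids <- samples
  }
  # dosage of the ALT allele from diploid GT strings
  alt_count <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) return(NA_real_)
      sum(as.numeric(x) > 0)
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, alt_count))
  if (nrow(gt) == 1) dos <- matrix(dos, nrow = 1)
  n_missing <- rowSums(is.na(dos))
  n_obs <- ncol(dos) - n_missing
  alt_af <- rowSums(dos, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  flipped <- alt_af > 0.5
  dos[flipped, ] <- 2 - dos[flipped, , drop = FALSE]
  mac <- rowSums(dos, na.rm = TRUE)
  maf <- mac / (2 * pmax(n_obs, 1))
  variants <- tibble(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                        fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    maf = maf, mac = mac, n_missing = n_missing, flipped = flipped)
  dosages <- t(dos)
  dimnames(dosages) <- list(ids, variants$variant_id)
  structure(list(ids = ids, dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Filter variants on minor allele frequency and count
#'
#' Keeps variants with `MAF < maf_max` (strict, so a variant at exactly 1%
#' is removed) and `MAC >= mac_min` (the default removes variants with three
#' or fewer minor alleles). A per-rule filter log is attached.
#'
#' @param g a `genotype_matrix`.
#' @param maf_max exclusive MAF upper bound (default 0.01).
#' @param mac_min inclusive MAC lower bound (default 4).
#' @return the filtered `genotype_matrix`, with attribute `"filter_log"`
#'   (tibble: variant_id, maf, mac, pass_maf, pass_mac, kept). Errors if no
#'   variant survives.
#' @export
filter_variants <- function(g, maf_max = 0.01, mac_min = 4) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  pass_maf <- v$maf < maf_max
  pass_mac <- v$mac >= mac_min
  kept <- pass_maf & pass_mac
  log <- tibble(variant_id = v$variant_id, maf = v$maf, mac = v$mac,
                pass_maf = pass_maf, pass_mac = pass_mac, kept = kept)
  if (!any(kept)) {
    abort(sprintf(paste0(
      "no variant passes MAF < %g and MAC >= %d; ",
      "check thresholds against the cohort's allele-frequency spectrum"),
      maf_max, mac_min))
  }
  out <- structure(list(ids = g$ids,
                        dosages = g$dosages[, kept, drop = FALSE],
                        variants = v[kept, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "filter_log") <- log
  out
}

#' Group qualified variants into per-gene variant sets
#'
#' @param g a filtered `genotype_matrix`.
#' @param gene_map data frame with columns `variant_id`, `gene_id`; variants
#'   mapping to several genes contribute to each. Unmapped variants are
#'   counted and dropped (message, not an error).
#' @param min_variants genes need at least this many qualified variants
#'   (default 2).
#' @return a named list of `gene_variant_set`s: each a list with `gene_id`,
#'   `variant_ids` (ordered by chrom, pos), `dosages` (n x m), `mafs`,
#'   `weights` (from [variant_weights()] at the default Beta(1, 25)).
#' @export
group_by_gene <- function(g, gene_map, min_variants = 2) {
  stopifnot(inherits(g, "genotype_matrix"))
  gene_map <- as_tibble(gene_map)
  mapped <- gene_map$variant_id %in% g$variants$variant_id
  unmapped <- setdiff(g$variants$variant_id, gene_map$variant_id)
  if (length(unmapped)) {
    inform(sprintf("%d qualified variant(s) not mapped to any gene",
                   length(unmapped)))
  }
  gm <- gene_map[mapped, , drop = FALSE]
  sets <- list()
  for (gid in unique(gm$gene_id)) {
    vids <- gm$variant_id[gm$gene_id == gid]
    cols <- match(vids, g$variants$variant_id)
    ord <- order(g$variants$chrom[cols], g$variants$pos[cols])
    vids <- vids[ord]
    cols <- cols[ord]
    if (length(vids) < min_variants) next
    mafs <- g$variants$maf[cols]
    sets[[gid]] <- structure(list(
      gene_id = gid, variant_ids = vids,
      dosages = g$dosages[, cols, drop = FALSE],
      mafs = mafs, weights = variant_weights(mafs)),
      class = "gene_variant_set")
  }
  if (!length(sets)) {
    abort(sprintf("no gene has at least %d qualified variants", min_variants))
  }
  sets[order(names(sets))]
}

#' Beta-density variant weights
#'
#' Up-weights rarer variants: `w_j = dbeta(MAF_j; a, b)`. The default
#' Beta(1, 25) is the SKAT-family convention and is strictly decreasing
#' in MAF; `a = b = 1` gives equal weights.
#'
#' @param mafs minor allele frequencies in `(0, 0.5]`.
#' @param beta_a,beta_b Beta density parameters (defaults 1, 25).
#' @return positive weights, same length as `mafs`.
#' @export
variant_weights <- function(mafs, beta_a = 1, beta_b = 25) {
  if (any(mafs <= 0)) {
    abort("MAF = 0 (monomorphic) variants must be filtered before weighting")
  }
  stopifnot(all(mafs <= 0.5))
  dbeta(mafs, beta_a, beta_b)
}

# impute missing dosages to 2*MAF (testing convention) and drop variants
# monomorphic in the analysis sample
impute_dosages <- function(dosages, mafs) {
  for (j in seq_len(ncol(dosages))) {
    nas <- is.na(dosages[, j])
    if (any(nas)) dosages[nas, j] <- 2 * mafs[j]
  }
  dosages
}
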