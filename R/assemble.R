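#' Assemble the result bundle of a scan
#'
#' Produces the publication-style result tables from a gene-by-module scan:
#' the significant-gene table (modules passing the threshold, best p per
#' gene), the composite-Manhattan export (every gene contributes one
#' omnibus p per module), per-gene module-heat data, and the Q-Q pairing of
#' all omnibus p-values against the uniform quantiles.
#'
#' @param scan a `facemod_scan` tibble from [scan_genes()].
#' @param plan a `multiplicity_plan`.
#' @param effects optional tibble of effect sizes (from
#'   [effect_size_centroid()]) to join onto the significant-gene table.
#' @return a `facemod_report`: list with `significant` (tibble),
#'   `manhattan` (tibble), `module_heat` (tibble), `qq` (tibble),
#'   `threshold`, `plan`.
#' @export
assemble_report <- function(scan, plan, effects = NULL) {
  stopifnot(inherits(plan, "multiplicity_plan"))
  scan <- as_tibble(scan)
  thr <- plan$threshold
  sig <- dplyr::filter(scan, .data$p_omnibus < thr)
  significant <- if (nrow(sig)) {
    out <- dplyr::summarise(
      dplyr::group_by(sig, .data$gene_id),
      modules = paste(sort(unique(.data$module_id)), collapse = ","),
      best_module = .data$module_id[which.min(.data$p_omnibus)],
      best_p = min(.data$p_omnibus), .groups = "drop")
    dplyr::arrange(out, .data$best_p)
  } else {
    tibble(gene_id = character(), modules = character(),
           best_module = integer(), best_p = numeric())
  }
  if (!is.null(effects) && nrow(significant)) {
    significant <- dplyr::left_join(significant, effects, by = "gene_id")
  }
  manhattan <- dplyr::select(scan, "gene_id", "module_id", "p_omnibus")
  heat <- dplyr::mutate(manhattan, neg_log10_p = -log10(.data$p_omnibus))
  n <- nrow(scan)
  ord <- order(scan$p_omnibus)
  qq <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = sort(-log10(scan$p_omnibus), decreasing = TRUE))
  structure(list(significant = significant, manhattan = manhattan,
                 module_heat = heat, qq = qq, threshold = thr, plan = plan),
            class = "facemod_report")
}

#' @export
print.facemod_report <- function(x, ...) {
  cat(sprintf("<facemod_report> %d gene-module tests, threshold %s\n",
              nrow(x$manhattan), format(signif(x$threshold, 2))))
  cat(sprintf("  significant genes: %d\n", nrow(x$significant)))
  if (nrow(x$significant)) print(x$significant)
  invisible(x)
}

#' Write the report tables as TSV plus a JSON manifest
#' @param report a `facemod_report`.
#' @param dir output directory (created if missing).
#' @param seed seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$significant, "significant_genes.tsv")
  wt(report$manhattan, "manhattan.tsv")
  wt(report$module_heat, "module_heat.tsv")
  wt(report$qq, "qq.tsv")
  jsonlite::write_json(
    list(n_genes = report$plan$n_genes, m_eff = report$plan$m_eff,
         m_eff_raw = report$plan$m_eff_raw, alpha = report$plan$alpha,
         threshold = report$threshold, seed = seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
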