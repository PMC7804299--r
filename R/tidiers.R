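# broom-style verbs and ggplot2 views for the main result types.

#' Tidy a gene-by-module scan
#'
#' One row per (gene, module, kernel) with the kernel label in a column —
#' the long form convenient for dplyr/ggplot2 work. `glance()` gives the
#' one-row-per-scan summary.
#'
#' @param x a `facemod_scan`.
#' @param ... unused.
#' @return a tibble: `gene_id`, `module_id`, `kernel`, `p_value`.
#' @export
tidy.facemod_scan <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "gene_id", "module_id",
                  dplyr::starts_with("p_")),
    cols = dplyr::starts_with("p_"), names_to = "kernel",
    names_prefix = "p_", values_to = "p_value")
  dplyr::arrange(long, .data$gene_id, .data$module_id)
}

#' @rdname tidy.facemod_scan
#' @export
glance.facemod_scan <- function(x, ...) {
  x <- as_tibble(x)
  tibble(n_tests = nrow(x),
         n_genes = dplyr::n_distinct(x$gene_id),
         n_modules = dplyr::n_distinct(x$module_id),
         min_p_omnibus = min(x$p_omnibus),
         lambda_gc = median(qchisq(x$p_omnibus, df = 1,
                                   lower.tail = FALSE)) /
           qchisq(0.5, df = 1, lower.tail = FALSE))
}

#' Composite Manhattan-style plot of a scan
#'
#' Every gene contributes one omnibus p-value per module; genes are ordered
#' along the x axis and all module points are overplotted, mirroring the
#' composite view used for hierarchical module phenotypes.
#'
#' @param object a `facemod_scan`.
#' @param threshold optional significance threshold drawn as a line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.facemod_scan <- function(object, threshold = NULL, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      gene_index = as.integer(factor(.data$gene_id)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_index,
                                        y = -log10(.data$p_omnibus))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "gene", y = expression(-log[10](italic(p))),
                  title = "Gene-based omnibus association across modules") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 colour = "red", linetype = 2)
  }
  p
}

#' Q-Q plot of the omnibus p-values of a report
#' @param object a `facemod_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.facemod_report <- function(object, ...) {
  ggplot2::ggplot(object$qq,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Heat view of one gene's module-wise association
#' @param scan a `facemod_scan`.
#' @param gene_id gene to display.
#' @param hierarchy optional `segment_hierarchy` to facet by level.
#' @return a ggplot object.
#' @export
plot_module_heat <- function(scan, gene_id, hierarchy = NULL) {
  df <- dplyr::filter(as_tibble(scan), .data$gene_id == !!gene_id)
  if (!is.null(hierarchy)) {
    df <- dplyr::left_join(
      df, dplyr::select(as_tibble(hierarchy), "segment_id", "level"),
      by = c(module_id = "segment_id"))
  } else df$level <- 0L
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$module_id),
                                   y = factor(.data$level),
                                   fill = -log10(.data$p_omnibus))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "module", y = "hierarchy level",
                  fill = expression(-log[10](italic(p))),
                  title = gene_id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
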