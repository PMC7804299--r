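#' Derive all module phenotypes from raw landmarks
#'
#' The full phenotyping stage: builds (or reuses) the segment hierarchy,
#' then for every segment re-runs GPA restricted to its landmarks, performs
#' PCA, retains components by parallel analysis, and residualizes the
#' retained scores on the covariates. The result is one multivariate
#' phenotype per segment, ready for kernel association testing.
#'
#' @param faces a raw [landmark_set()].
#' @param covariates covariate table (first column `id`); pass `NULL` to
#'   skip adjustment.
#' @param hierarchy an existing `segment_hierarchy` to reuse (frozen segment
#'   boundaries); `NULL` (default) re-estimates it from `faces`.
#' @param n_levels hierarchy depth when estimating (default 5).
#' @param n_perm,percentile parallel-analysis settings (see
#'   [parallel_analysis()]).
#' @param seed integer seed (permutation streams are derived per segment).
#' @return an object of class `module_phenotype_set`: list with `hierarchy`,
#'   `modules` (named list of `module_phenotype`, one per segment),
#'   `mean_shape`, `centroid_sizes`.
#' @examples
#' cfg <- synth_config(n_individuals = 50, n_landmarks = 64, n_levels = 3)
#' co <- simulate_cohort(cfg)
#' ph <- phenotype_modules(co$faces, co$covariates, n_levels = 3,
#'                         n_perm = 20, seed = 7)
#' length(ph$modules)
#' @export
phenotype_modules <- function(faces, covariates = NULL, hierarchy = NULL,
                              n_levels = 5, n_perm = 100, percentile = 0.95,
                              seed = 1L) {
  stopifnot(inherits(faces, "landmark_set"))
  full <- gpa_align(faces)
  if (is.null(hierarchy)) {
    hierarchy <- build_hierarchy(faces, n_levels = n_levels)
  }
  modules <- vector("list", nrow(hierarchy))
  names(modules) <- as.character(hierarchy$segment_id)
  for (i in seq_len(nrow(hierarchy))) {
    sid <- hierarchy$segment_id[i]
    idx <- hierarchy$landmarks[[i]]
    al <- gpa_align(subset_landmarks(faces, idx))$aligned
    ph <- module_pca(al, segment_id = sid)
    X <- sweep(flatten_coords(al$coords), 2, ph$center)
    k <- parallel_analysis(X, n_perm = n_perm, percentile = percentile,
                          seed = stage_seed(seed, paste0("pa_", sid)))
    k <- min(k, ncol(ph$scores))
    ph$scores <- ph$scores[, seq_len(k), drop = FALSE]
    ph$eigenvalues <- ph$eigenvalues[seq_len(k)]
    ph$loadings <- ph$loadings[, seq_len(k), drop = FALSE]
    if (!is.null(covariates)) ph <- pls_adjust(ph, covariates)
    modules[[i]] <- ph
  }
  structure(list(hierarchy = hierarchy, modules = modules,
                 mean_shape = full$mean_shape,
                 centroid_sizes = full$aligned$centroid_sizes,
                 ids = faces$ids),
            class = "module_phenotype_set")
}

#' @export
print.module_phenotype_set <- function(x, ...) {
  ks <- vapply(x$modules, function(m) ncol(m$scores), integer(1))
  cat(sprintf("<module_phenotype_set> %d modules, %d individuals, %d-%d PCs\n",
              length(x$modules), length(x$ids), min(ks), max(ks)))
  invisible(x)
}

#' Per-module retained-PC summary
#' @param x a `module_phenotype_set`.
#' @param ... unused.
#' @return a tibble: `segment_id`, `level`, `n_landmarks`, `n_pcs`,
#'   `var_explained` (sum of retained eigenvalues).
#' @export
glance.module_phenotype_set <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$modules), function(i) {
    m <- x$modules[[i]]
    tibble(segment_id = x$hierarchy$segment_id[i],
           level = x$hierarchy$level[i],
           n_landmarks = length(x$hierarchy$landmarks[[i]]),
           n_pcs = ncol(m$scores),
           var_explained = sum(m$eigenvalues))
  }))
}

#' Write module phenotype scores as TSV (one file per module)
#' @param x a `module_phenotype_set`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phenotypes <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in x$modules) {
    df <- data.frame(id = m$ids, m$scores)
    colnames(df) <- c("id", paste0("PC", seq_len(ncol(m$scores))))
    write.table(df, file.path(dir, sprintf("module_%02d.tsv", m$segment_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
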