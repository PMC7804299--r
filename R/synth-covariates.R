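#' Generate a covariate table and plant its shape effects
#'
#' Produces the covariate set the analysis adjusts for: `sex` (binary), `age`
#' (years), `height` (cm), `weight` (kg), `size` (facial centroid size,
#' computed from the supplied faces) and `n_ancestry_pcs` ancestry principal
#' components (standard normal). Each covariate with a non-zero magnitude in
#' `config$covariate_effects` displaces every face linearly along a fixed
#' full-face unit field by `magnitude` mm per standardized covariate unit.
#'
#' @param config a [synth_config()].
#' @param faces a [landmark_set()]; required for the facial-size column and
#'   as the target of the planted effects.
#' @param truth the matching `face_ground_truth` (per-individual transforms,
#'   so effects are applied in each individual's own frame).
#' @return a list with `covariates` (tibble, first column `id`) and `faces`
#'   (the displaced landmark set).
#' @export
generate_covariates <- function(config, faces, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(faces, "landmark_set"))
  n <- config$n_individuals
  L <- config$n_landmarks
  with_seed(stage_seed(config$seed, "covariates"), {
    cov_tbl <- tibble(
      id = faces$ids,
      sex = rbinom(n, 1, 0.5),
      age = runif(n, 3, 40),
      height = rnorm(n, 165, 10),
      weight = rnorm(n, 65, 12))
    for (k in seq_len(config$n_ancestry_pcs)) {
      cov_tbl[[paste0("ancestry_pc", k)]] <- rnorm(n)
    }
    eff <- config$covariate_effects
    planted_cols <- setdiff(names(cov_tbl), "id")
    for (cn in planted_cols) {
      mag <- if (grepl("^ancestry_pc", cn)) unname(eff["ancestry"])
             else unname(eff[cn])
      if (is.na(mag) || mag == 0) next
      U <- matrix(rnorm(L * 3), L, 3)
      U <- U / sqrt(sum(U^2))
      zc <- as.numeric(scale(cov_tbl[[cn]]))
      for (i in seq_len(n)) {
        Ui <- truth$scales[i] * mag * zc[i] * U %*% t(truth$rotations[[i]])
        faces$coords[i, , ] <- faces$coords[i, , ] + Ui
      }
    }
    # facial size measured after all effects are in place
    cov_tbl$size <- vapply(seq_len(n),
                           function(i) centroid_size(faces$coords[i, , ]),
                           numeric(1))
    list(covariates = cov_tbl, faces = faces)
  })
}
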