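# Synthetic face generator: template patch, ground-truth segment tree,
# nested low-rank deformation fields, iid noise, random rigid perturbation.

# regular g x g grid embedded as a curved patch (a smooth dome), mm units
face_template <- function(n_landmarks, spacing = 4) {
  g <- as.integer(sqrt(n_landmarks))
  ix <- rep(seq_len(g), times = g)
  iy <- rep(seq_len(g), each = g)
  x <- (ix - (g + 1) / 2) * spacing
  y <- (iy - (g + 1) / 2) * spacing
  half <- (g - 1) / 2 * spacing
  z <- 0.35 * half * (1 - (x^2 + y^2) / (2 * half^2))
  list(coords = cbind(x = x, y = y, z = z), ix = ix, iy = iy, g = g)
}

# ground-truth binary hierarchy on the grid: recursive half-split along the
# axis of larger extent; node k has children 2k and 2k+1; levels 0..d-1
template_hierarchy <- function(template, n_levels) {
  segs <- list()
  recurse <- function(id, level, idx) {
    segs[[length(segs) + 1]] <<- list(
      segment_id = id, level = level,
      parent_id = if (id == 1) NA_integer_ else id %/% 2,
      landmarks = sort(idx))
    if (level + 1 >= n_levels) return(invisible())
    ex_x <- diff(range(template$ix[idx]))
    ex_y <- diff(range(template$iy[idx]))
    ax <- if (ex_y > ex_x) template$iy[idx] else template$ix[idx]
    cut <- median(range(ax)) # geometric midline of the block
    a <- idx[ax <= cut]
    b <- idx[ax > cut]
    recurse(2L * id, level + 1L, a)
    recurse(2L * id + 1L, level + 1L, b)
  }
  recurse(1L, 0L, seq_len(nrow(template$coords)))
  segs[order(vapply(segs, `[[`, 1L, "segment_id"))]
}

#' Generate synthetic faces with hierarchically structured shape covariance
#'
#' Draws `n_individuals` landmark configurations as: template patch + nested
#' low-rank deformation fields (one set of `deform_rank` unit basis fields per
#' segment-tree node, confined to that node's landmarks, with per-individual
#' Gaussian coefficients of per-level SD `deform_sd`) + iid landmark noise +
#' a per-individual random rigid transform and scale. The planted tree,
#' leaf labels and applied transforms are returned as ground truth so that
#' parameter-recovery tests are possible.
#'
#' @param config a [synth_config()].
#' @return a list with elements `faces` (a [landmark_set()]) and `truth`
#'   (class `face_ground_truth`: `segments`, `leaf_assignment`,
#'   `rotations`, `translations`, `scales`, `template`).
#' @examples
#' cfg <- synth_config(n_individuals = 20, n_landmarks = 64, n_levels = 3)
#' gf <- generate_faces(cfg)
#' dim(gf$faces)
#' @export
generate_faces <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(stage_seed(config$seed, "faces"), {
    n <- config$n_individuals
    L <- config$n_landmarks
    tmpl <- face_template(L)
    segs <- template_hierarchy(tmpl, config$n_levels)

    coords <- array(rep(tmpl$coords, each = n), dim = c(n, L, 3))
    # nested deformations: each node adds rank-r fields on its landmarks
    for (s in segs) {
      sdl <- config$deform_sd[s$level + 1]
      if (sdl <= 0) next
      m <- length(s$landmarks)
      for (r in seq_len(config$deform_rank)) {
        B <- matrix(rnorm(m * 3), m, 3)
        B <- B / sqrt(sum(B^2)) # unit Frobenius norm field
        coef <- rnorm(n, sd = sdl)
        for (a in 1:3) {
          coords[, s$landmarks, a] <-
            coords[, s$landmarks, a] + outer(coef, B[, a])
        }
      }
    }
    if (config$noise_sd > 0) {
      coords <- coords + array(rnorm(n * L * 3, sd = config$noise_sd),
                               dim = c(n, L, 3))
    }

    # per-individual rigid perturbation + scale (GPA must undo these)
    max_ang <- config$max_rotation_deg * pi / 180
    rots <- vector("list", n)
    trans <- matrix(0, n, 3)
    scales <- runif(n, config$scale_range[1], config$scale_range[2])
    for (i in seq_len(n)) {
      R <- if (max_ang > 0) random_rotation(max_ang) else diag(3)
      t_i <- if (config$translate_sd > 0) {
        rnorm(3, sd = config$translate_sd)
      } else c(0, 0, 0)
      rots[[i]] <- R
      trans[i, ] <- t_i
      coords[i, , ] <- scales[i] * coords[i, , ] %*% t(R) +
        matrix(t_i, L, 3, byrow = TRUE)
    }

    leaf_level <- config$n_levels - 1
    leaves <- Filter(function(s) s$level == leaf_level, segs)
    leaf_assignment <- integer(L)
    for (lf in leaves) leaf_assignment[lf$landmarks] <- lf$segment_id

    truth <- structure(list(
      segments = segs, leaf_assignment = leaf_assignment,
      rotations = rots, translations = trans, scales = scales,
      template = tmpl, causal_genes = character(0)),
      class = "face_ground_truth")
    list(faces = landmark_set(coords), truth = truth)
  })
}

#' Plant a gene effect on carriers' faces
#'
#' Individuals carrying at least one minor allele at any variant of the gene
#' are displaced along a fixed unit direction field confined to the target
#' segment's landmarks, scaled by `magnitude` (mm; the displacement norm in
#' the individual's own pre-transform frame). The field is applied in each
#' individual's frame using the recorded rigid transform, so the signal is
#' coherent after Procrustes alignment. Non-carriers are untouched.
#'
#' @param faces a [landmark_set()] from [generate_faces()].
#' @param genotypes a genotype set from [generate_genotypes()].
#' @param effect a list with `gene_id`, `segment_id`, `magnitude`.
#' @param truth the `face_ground_truth` for `faces`.
#' @return the modified `landmark_set`; the applied field, carrier flags and
#'   gene id are recorded in `attr(, "planted")` (a list, one entry per call).
#' @export
plant_gene_effect <- function(faces, genotypes, effect, truth) {
  stopifnot(inherits(faces, "landmark_set"),
            inherits(truth, "face_ground_truth"))
  seg <- Filter(function(s) s$segment_id == effect$segment_id,
                truth$segments)
  if (length(seg) == 0) abort(sprintf("unknown segment_id %s",
                                      effect$segment_id))
  seg <- seg[[1]]
  vids <- genotypes$gene_map$variant_id[
    genotypes$gene_map$gene_id == effect$gene_id]
  if (length(vids) == 0) abort(sprintf("unknown gene_id %s", effect$gene_id))
  dos <- genotypes$dosages[, vids, drop = FALSE]
  carriers <- rowSums(dos) >= 1
  if (!any(carriers)) {
    warn(sprintf("gene %s has no carriers; faces unchanged", effect$gene_id))
    return(faces)
  }
  if (effect$magnitude != 0) {
    m <- length(seg$landmarks)
    U <- with_seed(
      stage_seed(attr(genotypes, "seed") %||% 0L,
                 paste0("effect_", effect$gene_id, "_", effect$segment_id)), {
        U <- matrix(rnorm(m * 3), m, 3)
        U / sqrt(sum(U^2))
      })
    for (i in which(carriers)) {
      Ui <- truth$scales[i] * effect$magnitude * U %*% t(truth$rotations[[i]])
      faces$coords[i, seg$landmarks, ] <-
        faces$coords[i, seg$landmarks, ] + Ui
    }
    planted <- attr(faces, "planted") %||% list()
    planted[[length(planted) + 1]] <- list(
      gene_id = effect$gene_id, segment_id = effect$segment_id,
      magnitude = effect$magnitude, field = U, carriers = carriers)
    attr(faces, "planted") <- planted
  }
  faces
}
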