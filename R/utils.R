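# Internal helpers shared across stages.

#' Derive a stage-specific seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream so that adding or
#' re-running one stage never perturbs another. The stage name is hashed
#' (polynomial rolling hash over the UTF-8 bytes) and folded into the master
#' seed modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps everything in integer range
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer((as.numeric(seed) %% m + h) %% m)
}

# run expr with a locally-set seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# centroid size of a single L x 3 configuration: sqrt of summed squared
# distances of landmarks to their centroid
centroid_size <- function(conf) {
  cen <- colMeans(conf)
  sqrt(sum(sweep(conf, 2, cen)^2))
}

# flatten n x L x 3 -> n x 3L (x1 y1 z1 x2 y2 z2 ...) and back
flatten_coords <- function(coords) {
  n <- dim(coords)[1]; L <- dim(coords)[2]
  out <- matrix(aperm(coords, c(1, 3, 2)), nrow = n)
  # aperm gives n x 3 x L; matrix() stacks columns: x of lm1, y of lm1, z of lm1, ...
  out
}

unflatten_coords <- function(flat, L) {
  n <- nrow(flat)
  aperm(array(flat, dim = c(n, 3, L)), c(1, 3, 2))
}

# random rotation matrix with angle <= max_angle (radians), det +1
random_rotation <- function(max_angle) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, -max_angle, max_angle)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
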