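#' Landmark set container
#'
#' Holds an `n x L x 3` array of homologous quasi-landmark coordinates
#' (mm units), one configuration per individual, plus individual identifiers
#' and alignment state. Landmark `l` represents the same facial position in
#' every individual.
#'
#' @param coords numeric `n x L x 3` array.
#' @param ids character vector of individual identifiers (length n).
#' @param aligned has generalized Procrustes alignment been applied?
#' @param centroid_sizes pre-scaling centroid sizes (present iff aligned).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, ids = NULL, aligned = FALSE,
                         centroid_sizes = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (any(!is.finite(coords))) abort("landmark coordinates must be finite")
  n <- dim(coords)[1]
  if (is.null(ids)) ids <- sprintf("id%04d", seq_len(n))
  stopifnot(length(ids) == n)
  if (aligned && is.null(centroid_sizes)) {
    abort("aligned landmark sets must carry centroid sizes")
  }
  structure(list(ids = as.character(ids), coords = coords,
                 aligned = isTRUE(aligned),
                 centroid_sizes = centroid_sizes),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<landmark_set> %d individuals x %d landmarks x 3 (%s)\n",
              d[1], d[2], if (x$aligned) "aligned" else "raw"))
  invisible(x)
}

#' @export
dim.landmark_set <- function(x) dim(x$coords)

#' Convert a landmark set to a long tibble
#'
#' One row per (individual, landmark): columns `id`, `landmark`, `x`, `y`,
#' `z`. Useful for plotting and joins.
#'
#' @param x a `landmark_set`.
#' @param ... unused.
#' @return a tibble with `n * L` rows.
#' @export
tidy.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  tibble(
    id = rep(x$ids, times = d[2]),
    landmark = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(x$coords[, , 1]),
    y = as.vector(x$coords[, , 2]),
    z = as.vector(x$coords[, , 3]))
}

#' Write / read a landmark set as plain TSV
#'
#' Wide layout: one row per individual, first column `id`, then columns
#' `x_1 y_1 z_1 x_2 y_2 z_2 ...` for the L landmarks. The file round-trips
#' losslessly at full double precision.
#'
#' @param x a `landmark_set`.
#' @param path file path.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a `landmark_set`.
#' @export
write_landmarks <- function(x, path) {
  stopifnot(inherits(x, "landmark_set"))
  L <- dim(x$coords)[2]
  flat <- flatten_coords(x$coords)
  colnames(flat) <- as.vector(t(outer(seq_len(L), c("x", "y", "z"),
                                      function(i, a) paste0(a, "_", i))))
  df <- data.frame(id = x$ids, flat, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  flat <- as.matrix(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) flat <- matrix(flat, nrow = 1)
  landmark_set(unflatten_coords(flat, ncol(flat) / 3), ids = ids)
}
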