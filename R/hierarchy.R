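#' Build the global-to-local segment hierarchy
#'
#' Starting from the full face (level 0), each node is processed by re-running
#' GPA restricted to its landmarks, computing the RV-coefficient landmark
#' similarity, and bipartitioning it spectrally; the two children are then
#' recursed into until `n_levels` levels exist. A full `d`-level hierarchy
#' has `2^d - 1` segments (31 for the default 5 levels). Nodes smaller than
#' `min_split` landmarks are not split further; the hierarchy is then
#' reported incomplete via a warning.
#'
#' @param landmarks a [landmark_set()] (raw or aligned; each node runs its
#'   own GPA on its landmark subset).
#' @param n_levels hierarchy depth (default 5).
#' @param min_split minimum number of landmarks a node needs to be split
#'   (default 8).
#' @return a `segment_hierarchy`: a tibble with columns `segment_id`,
#'   `level`, `parent_id` and `landmarks` (list-column of integer index
#'   sets), with attributes `n_levels` and `complete`.
#' @examples
#' cfg <- synth_config(n_individuals = 60, n_landmarks = 64, n_levels = 3)
#' h <- build_hierarchy(generate_faces(cfg)$faces, n_levels = 3)
#' nrow(h) # 7 segments
#' @export
build_hierarchy <- function(landmarks, n_levels = 5, min_split = 8) {
  stopifnot(inherits(landmarks, "landmark_set"), n_levels >= 1)
  rows <- list()
  complete <- TRUE
  recurse <- function(id, level, idx) {
    rows[[length(rows) + 1]] <<- list(
      segment_id = id, level = level,
      parent_id = if (id == 1L) NA_integer_ else id %/% 2L,
      landmarks = sort(idx))
    if (level + 1 >= n_levels) return(invisible())
    if (length(idx) < min_split) {
      complete <<- FALSE
      return(invisible())
    }
    sub <- subset_landmarks(landmarks, idx)
    al <- gpa_align(sub)$aligned
    sim <- landmark_similarity(al)
    parts <- spectral_bipartition(sim, indices = idx)
    recurse(2L * id, level + 1L, parts$a)
    recurse(2L * id + 1L, level + 1L, parts$b)
  }
  recurse(1L, 0L, seq_len(dim(landmarks)[2]))
  if (!complete) {
    warn("hierarchy incomplete: some nodes were too small to split")
  }
  tbl <- dplyr::arrange(dplyr::bind_rows(lapply(rows, function(r) {
    tibble(segment_id = r$segment_id, level = r$level,
           parent_id = r$parent_id, landmarks = list(r$landmarks))
  })), .data$segment_id)
  structure(tbl, n_levels = n_levels, complete = complete,
            class = c("segment_hierarchy", class(tbl)))
}

#' Landmark index set of one segment
#' @param hierarchy a `segment_hierarchy`.
#' @param segment_id segment identifier.
#' @return integer vector of landmark indices.
#' @export
segment_landmarks <- function(hierarchy, segment_id) {
  i <- match(segment_id, hierarchy$segment_id)
  if (is.na(i)) abort(sprintf("unknown segment_id %s", segment_id))
  hierarchy$landmarks[[i]]
}

#' Export a segment hierarchy as JSON
#' @param hierarchy a `segment_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  obj <- list(
    n_levels = attr(hierarchy, "n_levels"),
    complete = attr(hierarchy, "complete"),
    segments = lapply(seq_len(nrow(hierarchy)), function(i) list(
      segment_id = hierarchy$segment_id[i], level = hierarchy$level[i],
      parent_id = if (is.na(hierarchy$parent_id[i])) NULL else
        hierarchy$parent_id[i],
      landmarks = hierarchy$landmarks[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segment hierarchy from JSON
#' @param path JSON path written by [write_hierarchy()].
#' @return a `segment_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  tbl <- dplyr::bind_rows(lapply(obj$segments, function(s) {
    tibble(segment_id = as.integer(s$segment_id),
           level = as.integer(s$level),
           parent_id = if (length(s$parent_id) != 1) NA_integer_ else
             as.integer(s$parent_id),
           landmarks = list(as.integer(unlist(s$landmarks))))
  }))
  structure(tbl, n_levels = obj$n_levels, complete = obj$complete,
            class = c("segment_hierarchy", class(tbl)))
}
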