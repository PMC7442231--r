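# Core containers: a polygonised tissue frame and a time-ordered sequence of
# frames with persistent cell indices.  These are plain lists with S3 classes,
# in the style of ape's "phylo": cheap to build in tests and easy to serialise.

#' Construct a polygonised tissue frame
#'
#' A frame holds the cell polygons, the cell-cell junctions (edges) and the
#' implied adjacency of one time point.  Adjacency is derived from the edges:
#' two cells are adjacent if and only if they share an edge; sharing a single
#' tissue vertex does not qualify.
#'
#' @param cells named list; each element a list with `id` (positive integer),
#'   `boundary` (N x 2 matrix, closed ring stored open) and
#'   `is_boundary_cell` (logical: touches the field-of-view border).
#' @param edges list; each element a list with `cells` (unordered pair of cell
#'   ids) and `polyline` (M x 2 matrix, M >= 2).
#' @param time acquisition time in seconds.
#' @return an object of class `epi_frame`.
#' @export
epi_frame <- function(cells, edges, time = 0) {
  ids <- vapply(cells, function(cl) as.integer(cl$id), integer(1))
  if (any(ids <= 0L)) stop("cell ids must be positive integers")
  names(cells) <- as.character(ids)
  pairs <- if (length(edges)) {
    t(vapply(edges, function(e) sort(as.integer(e$cells)), integer(2)))
  } else {
    matrix(integer(0), 0, 2)
  }
  structure(
    list(cells = cells, edges = edges, adj_pairs = pairs, time = time),
    class = "epi_frame"
  )
}

#' @export
print.epi_frame <- function(x, ...) {
  cat(sprintf("<epi_frame> %d cells, %d junctions, t = %.1f s\n",
              length(x$cells), length(x$edges), x$time))
  invisible(x)
}

#' Cell ids present in a frame
#' @param frame an `epi_frame`.
#' @return integer vector of cell ids.
#' @export
frame_cell_ids <- function(frame) {
  as.integer(names(frame$cells))
}

#' Adjacency of a frame as a pair list
#'
#' @param frame an `epi_frame`.
#' @return two-column integer matrix of adjacent cell-id pairs (a < b), one
#'   row per junction-sharing pair, deduplicated.
#' @export
frame_adjacency_pairs <- function(frame) {
  p <- frame$adj_pairs
  if (nrow(p) == 0L) return(p)
  unique(p)
}

#' Adjacency of a frame as a symmetric logical matrix
#'
#' @param frame an `epi_frame`.
#' @param ids cell ids to include (default: all cells in the frame).
#' @return symmetric logical matrix with dimnames = cell ids and FALSE
#'   diagonal.
#' @export
frame_adjacency_matrix <- function(frame, ids = frame_cell_ids(frame)) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  p <- frame_adjacency_pairs(frame)
  if (nrow(p)) {
    keep <- p[, 1L] %in% ids & p[, 2L] %in% ids
    p <- p[keep, , drop = FALSE]
    i <- match(p[, 1L], ids); j <- match(p[, 2L], ids)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Are two cells adjacent in a frame?
#' @param frame an `epi_frame`.
#' @param a,b cell ids.
#' @return logical.
#' @export
cells_adjacent <- function(frame, a, b) {
  p <- frame$adj_pairs
  lo <- min(a, b); hi <- max(a, b)
  any(p[, 1L] == lo & p[, 2L] == hi)
}

#' Find the junction between two cells
#' @param frame an `epi_frame`.
#' @param a,b cell ids.
#' @return the edge element, or NULL if the cells do not share a junction.
#' @export
frame_edge_between <- function(frame, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  idx <- which(frame$adj_pairs[, 1L] == lo & frame$adj_pairs[, 2L] == hi)
  if (!length(idx)) return(NULL)
  frame$edges[[idx[1L]]]
}

#' Construct a tissue sequence
#'
#' @param frames list of `epi_frame` objects with strictly increasing times.
#' @param pixel_size physical pixel edge length in micrometres (metadata; the
#'   polygons themselves are already in micrometres).
#' @return an object of class `tissue_sequence` with `dt_min`, the median
#'   inter-frame interval in minutes.
#' @export
tissue_sequence <- function(frames, pixel_size = 0.2405) {
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  dt_min <- if (length(times) > 1L) stats::median(diff(times)) / 60 else NA_real_
  structure(
    list(frames = frames, times = times, dt_min = dt_min,
         pixel_size = pixel_size),
    class = "tissue_sequence"
  )
}

#' @export
print.tissue_sequence <- function(x, ...) {
  cat(sprintf("<tissue_sequence> %d frames, %d cells in frame 1, dt = %.2f min\n",
              length(x$frames), length(x$frames[[1L]]$cells), x$dt_min))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `tissue_sequence`.
#' @return integer.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Per-cell presence across frames
#'
#' @param seq a `tissue_sequence`.
#' @return logical matrix frames x cells (columns named by cell id).
#' @export
cell_presence <- function(seq) {
  ids <- sort(unique(unlist(lapply(seq$frames, frame_cell_ids))))
  m <- vapply(seq$frames, function(f) ids %in% frame_cell_ids(f),
              logical(length(ids)))
  m <- t(m)
  colnames(m) <- ids
  m
}

# Stable text key for a set of cells ("1+4+7"), used as group identity.
group_key <- function(members) paste(sort(as.integer(members)), collapse = "+")

key_to_members <- function(key) as.integer(strsplit(key, "+", fixed = TRUE)[[1L]])
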