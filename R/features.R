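# Feature time series describing a tracked cell group: the six pairwise
# boundary distances for quartets (T1 search) and the single maximal pairwise
# boundary distance for rosettes.  Distances are minimal Euclidean distances
# between cell boundary polylines, so adjacent cells score exactly zero.

#' Feature schema
#'
#' Built-in extractors:
#' * `quartet_pairdist` (k = 4, d = 6): the six pairwise minimal boundary
#'   distances.  In the default `"sorted"` mode the six values are sorted in
#'   descending order at each frame, which makes templates transferable
#'   across quartets without fixing a cell-pair correspondence; `"lex"` keeps
#'   the lexicographic sorted-member pair order.
#' * `rosette_maxpairdist` (k = 5 or 6, d = 1): the maximal pairwise boundary
#'   distance.
#'
#' @param name one of `"quartet_pairdist"`, `"rosette_maxpairdist"`.
#' @param k group size.
#' @param mode `"sorted"` or `"lex"` (quartet extractor only).
#' @return a `feature_schema` list with fields `name`, `k`, `d`, `mode`.
#' @export
feature_schema <- function(name = c("quartet_pairdist", "rosette_maxpairdist"),
                           k = if (name == "quartet_pairdist") 4L else 5L,
                           mode = c("sorted", "lex")) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  d <- switch(name, quartet_pairdist = 6L, rosette_maxpairdist = 1L)
  if (name == "quartet_pairdist" && k != 4L) stop("quartet features need k = 4")
  if (name == "rosette_maxpairdist" && !k %in% c(5L, 6L)) {
    stop("rosette features need k = 5 or 6")
  }
  structure(list(name = name, k = as.integer(k), d = d, mode = mode),
            class = "feature_schema")
}

#' Minimal distance between two cell boundaries
#'
#' Segment-to-segment minimal Euclidean distance between the boundary
#' polygons of two cells; exactly 0 for adjacent cells (they share junction
#' geometry).
#'
#' @param a,b cell ids.
#' @param frame an `epi_frame` containing both cells.
#' @return distance in micrometres.
#' @export
boundary_distance <- function(a, b, frame) {
  ca <- frame$cells[[as.character(a)]]
  cb <- frame$cells[[as.character(b)]]
  if (is.null(ca) || is.null(cb)) stop("cell missing from frame")
  if (cells_adjacent(frame, a, b)) return(0)
  polyline_distance(ca$boundary, cb$boundary, closed_p = TRUE, closed_q = TRUE)
}

# All pairwise boundary distances of a member set in one frame, in
# lexicographic sorted-member pair-slot order.
.pair_distances <- function(members, frame, cache = NULL) {
  mem <- sort(members)
  prs <- pair_slots(length(mem))
  vapply(seq_len(nrow(prs)), function(s) {
    a <- mem[prs[s, 1L]]; b <- mem[prs[s, 2L]]
    if (!is.null(cache)) {
      key <- sprintf("%d_%d_%d", frame$time, a, b)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- boundary_distance(a, b, frame)
      cache[[key]] <- val
      return(val)
    }
    boundary_distance(a, b, frame)
  }, numeric(1))
}

#' Extract the feature time series of a tracked group
#'
#' @param members integer vector of cell ids (length = schema k).
#' @param seq a `tissue_sequence`.
#' @param schema a [feature_schema()].
#' @param frames integer vector of frame indices (default: all frames where
#'   every member is present; must be contiguous).
#' @param cache optional environment used to share per-(frame, pair) distance
#'   computations across overlapping groups.
#' @return a `candidate_series`: list with `members`, `values` (n x d
#'   matrix), `frames` (frame indices), `times` (seconds).
#' @export
extract_features <- function(members, seq, schema, frames = NULL,
                             cache = NULL) {
  if (length(members) != schema$k) stop("group size does not match schema k")
  if (is.null(frames)) {
    pres <- vapply(seq$frames, function(fr) {
      all(as.character(members) %in% names(fr$cells))
    }, logical(1))
    frames <- which(pres)
  }
  if (!length(frames)) stop("group not present in any requested frame")
  if (any(diff(frames) != 1L)) {
    stop("track has gaps; split it upstream before feature extraction")
  }
  vals <- matrix(NA_real_, length(frames), schema$d)
  for (r in seq_along(frames)) {
    fr <- seq$frames[[frames[r]]]
    if (!all(as.character(members) %in% names(fr$cells))) {
      stop("cell missing mid-track at frame ", frames[r])
    }
    d6 <- .pair_distances(members, fr, cache)
    vals[r, ] <- switch(schema$name,
      quartet_pairdist = if (schema$mode == "sorted") sort(d6, decreasing = TRUE) else d6,
      rosette_maxpairdist = max(d6)
    )
  }
  structure(list(members = sort(members), values = vals, frames = frames,
                 times = seq$times[frames]),
            class = "candidate_series")
}

#' Build a motif template from an example in a dataset
#'
#' Converts a representative example (a cell group over a frame interval)
#' into the feature time series used for matching, optionally with per-frame
#' phase labels (e.g. "contracting" / "transition" / "growing") that matching
#' transfers onto detected events.
#'
#' @param seq a `tissue_sequence`.
#' @param members cell ids of the example group.
#' @param frames contiguous frame interval of the example.
#' @param schema a [feature_schema()].
#' @param phases optional character vector of per-frame phase labels
#'   (length = length(frames)).
#' @return a `motif_template`: list with `values` (m x d), `times`, `phases`,
#'   `schema`.
#' @export
template_from_example <- function(seq, members, frames, schema,
                                  phases = NULL) {
  if (min(frames) < 1L || max(frames) > n_frames(seq)) {
    stop("template interval outside the sequence")
  }
  cs <- extract_features(members, seq, schema, frames = frames)
  if (!is.null(phases) && length(phases) != length(frames)) {
    stop("phases must have one label per template frame")
  }
  structure(list(values = cs$values, times = cs$times, phases = phases,
                 schema = schema),
            class = "motif_template")
}

#' @export
print.motif_template <- function(x, ...) {
  cat(sprintf("<motif_template> %d frames x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values), x$schema$name,
              if (!is.null(x$phases)) ", phase-labeled" else ""))
  invisible(x)
}

#' Write / read a template as CSV
#'
#' Columns: `frame`, `t_offset_s`, `f1..fd` and optionally `phase`.  The same
#' format carries hand-drawn templates.
#'
#' @param template a `motif_template`.
#' @param path file path.
#' @param schema a [feature_schema()] describing the features in the file.
#' @return `read_template` returns a `motif_template`.
#' @export
write_template <- function(template, path) {
  m <- nrow(template$values)
  df <- data.frame(frame = seq_len(m),
                   t_offset_s = template$times - template$times[1L])
  v <- as.data.frame(template$values)
  names(v) <- paste0("f", seq_len(ncol(v)))
  df <- cbind(df, v)
  if (!is.null(template$phases)) df$phase <- template$phases
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f\\d+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("f", "", fcols)))]
  if (length(fcols) != schema$d) {
    stop(sprintf("template has %d feature columns, schema expects %d",
                 length(fcols), schema$d))
  }
  structure(list(values = as.matrix(df[, fcols, drop = FALSE]),
                 times = df$t_offset_s,
                 phases = if ("phase" %in% names(df)) df$phase else NULL,
                 schema = schema),
            class = "motif_template")
}
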