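# Enumeration of connected induced k-cell subgraphs of the cell-adjacency
# graph, canonical topology classification for k <= 6, the enclosed-cell
# test, and assembly of temporally tracked candidate groups.
#
# Small-k graph machinery is deliberately dependency-free: topologies are
# encoded as bit masks over the sorted-member pair slots (pair (i,j), i < j,
# in lexicographic order -> bit 2^(slot-1)), which makes per-frame topology
# trajectories a vectorised table lookup.

# -- pair-slot helpers -------------------------------------------------------

pair_slots <- function(k) {
  # matrix with columns i, j over 1 <= i < j <= k, lexicographic
  ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij
}

mask_from_adj <- function(A) {
  # A: k x k logical adjacency -> integer mask
  k <- nrow(A)
  ij <- pair_slots(k)
  sum(2^(seq_len(nrow(ij)) - 1L) * A[ij])
}

adj_from_mask <- function(mask, k) {
  ij <- pair_slots(k)
  bits <- bitwAnd(mask %/% 2^(seq_len(nrow(ij)) - 1L), 1L) == 1L
  A <- matrix(FALSE, k, k)
  A[ij] <- bits
  A | t(A)
}

.epi_cache <- new.env(parent = emptyenv())

all_perms <- function(k) {
  key <- sprintf("perms%d", k)
  if (!is.null(.epi_cache[[key]])) return(.epi_cache[[key]])
  rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  p <- rec(seq_len(k))
  .epi_cache[[key]] <- p
  p
}

# Connectivity lookup: logical vector indexed by mask + 1.
connectivity_table <- function(k) {
  key <- sprintf("conn%d", k)
  if (!is.null(.epi_cache[[key]])) return(.epi_cache[[key]])
  n_masks <- 2^(k * (k - 1L) / 2L)
  out <- logical(n_masks)
  for (m in seq_len(n_masks) - 1L) {
    A <- adj_from_mask(m, k)
    seen <- logical(k); seen[1L] <- TRUE
    repeat {
      reach <- seen | (colSums(A & seen) > 0L)
      if (identical(reach, seen)) break
      seen <- reach
    }
    out[m + 1L] <- all(seen)
  }
  .epi_cache[[key]] <- out
  out
}

canonical_mask <- function(mask, k) {
  key <- sprintf("canon%d", k)
  tab <- .epi_cache[[key]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    .epi_cache[[key]] <- tab
  }
  mk <- as.character(mask)
  hit <- tab[[mk]]
  if (!is.null(hit)) return(hit)
  A <- adj_from_mask(mask, k)
  ij <- pair_slots(k)
  w <- 2^(seq_len(nrow(ij)) - 1L)
  best <- Inf
  for (p in all_perms(k)) {
    Ap <- A[p, p, drop = FALSE]
    v <- sum(w * Ap[ij])
    if (v < best) best <- v
  }
  tab[[mk]] <- best
  best
}

# -- spec-facing operations --------------------------------------------------

#' Enumerate all connected induced k-cell subgraphs of a frame
#'
#' Uses recursive extension with exclusive neighbourhoods (ESU-style), which
#' emits every connected induced vertex set of size `k` exactly once, in
#' deterministic sorted order.
#'
#' @param frame an `epi_frame`, or a symmetric logical adjacency matrix with
#'   cell-id dimnames.
#' @param k group size (>= 1).
#' @return integer matrix with `k` columns, one sorted group per row, rows in
#'   lexicographic order.  Zero rows when `k` exceeds the cell count.
#' @export
connected_induced_subgraphs <- function(frame, k) {
  stopifnot(k >= 1L)
  A <- if (inherits(frame, "epi_frame")) frame_adjacency_matrix(frame) else frame
  ids <- as.integer(rownames(A))
  n <- length(ids)
  if (k > n) return(matrix(integer(0), 0, k))
  if (k == 1L) return(matrix(sort(ids), ncol = 1L))
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  out <- list(); n_out <- 0L
  emit <- function(S) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- S
  }
  extend <- function(S, ext, blocked) {
    if (length(S) == k) { emit(S); return() }
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      excl <- nbrs[[w]]
      excl <- excl[!blocked[excl]]
      blocked2 <- blocked
      blocked2[excl] <- TRUE
      blocked2[w] <- TRUE
      extend(c(S, w), c(ext, excl), blocked2)
      # w stays blocked for subsequent branches of this level
      blocked[w] <- TRUE
    }
  }
  for (v in seq_len(n)) {
    blocked <- logical(n)
    blocked[seq_len(v)] <- TRUE
    ext <- nbrs[[v]]
    ext <- ext[ext > v]
    blocked[ext] <- TRUE
    extend(v, ext, blocked)
  }
  if (n_out == 0L) return(matrix(integer(0), 0, k))
  G <- do.call(rbind, lapply(out[seq_len(n_out)], function(S) sort(ids[S])))
  G[do.call(order, split(G, col(G))), , drop = FALSE]
}

#' Canonical topology class of a cell group
#'
#' Two groups receive the same class id if and only if their induced
#' adjacency graphs are isomorphic.  The canonical form is the minimum
#' adjacency bit mask over all k! vertex permutations (k <= 6), cached.
#'
#' @param members integer vector of k cell ids.
#' @param frame an `epi_frame` (or adjacency matrix) containing the cells.
#' @return character class id, e.g. `"k4-c13"`.
#' @export
topology_class <- function(members, frame) {
  k <- length(members)
  A <- if (inherits(frame, "epi_frame")) frame_adjacency_matrix(frame) else frame
  miss <- setdiff(as.character(members), rownames(A))
  if (length(miss)) stop("cells absent from frame: ", paste(miss, collapse = ", "))
  idx <- match(as.character(sort(members)), rownames(A))
  mask <- mask_from_adj(A[idx, idx, drop = FALSE])
  sprintf("k%d-c%d", k, canonical_mask(mask, k))
}

#' Inventory of connected topology classes of size k
#'
#' @param k group size (<= 6 recommended).
#' @return character vector of the distinct class ids of all connected graphs
#'   on k vertices.
#' @export
topology_class_inventory <- function(k) {
  conn <- connectivity_table(k)
  masks <- which(conn) - 1L
  sort(unique(vapply(masks, function(m) sprintf("k%d-c%d", k, canonical_mask(m, k)),
                     character(1))))
}

# Reference class ids for the T1-relevant quartet topologies: the diamond
# (K4 minus one edge; the before/after states) and the 4-cycle (the
# four-way-vertex state).
t1_allowed_classes <- function() {
  diamond <- matrix(TRUE, 4, 4); diag(diamond) <- FALSE
  diamond[3, 4] <- diamond[4, 3] <- FALSE
  cyc <- matrix(FALSE, 4, 4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    cyc[p[1], p[2]] <- cyc[p[2], p[1]] <- TRUE
  }
  c(diamond = sprintf("k4-c%d", canonical_mask(mask_from_adj(diamond), 4L)),
    cycle4 = sprintf("k4-c%d", canonical_mask(mask_from_adj(cyc), 4L)))
}

#' Does a group enclose a non-member cell?
#'
#' A group encloses a cell when that cell (or a small pocket of cells) is
#' completely walled in by group members.  Combinatorially: some connected
#' component of the non-member cells contains no field-of-view boundary cell,
#' so it cannot reach the tissue margin except through the group.
#'
#' @param members integer vector of cell ids.
#' @param frame an `epi_frame` with boundary-cell flags.
#' @return logical flag.
#' @export
has_enclosed_nonmember <- function(members, frame) {
  A <- frame_adjacency_matrix(frame)
  ids <- as.integer(rownames(A))
  outside <- !(ids %in% members)
  if (!any(outside)) return(FALSE)
  is_bnd <- vapply(frame$cells[as.character(ids)],
                   function(cl) isTRUE(cl$is_boundary_cell), logical(1))
  sub <- which(outside)
  # connected components of the non-member cells
  comp <- integer(length(sub))
  cur <- 0L
  for (s in seq_along(sub)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[sub[i], sub] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  for (cc in seq_len(cur)) {
    if (!any(is_bnd[sub[comp == cc]])) return(TRUE)
  }
  FALSE
}

# -- tracked candidate groups ------------------------------------------------

#' Enumerate candidate groups over a whole sequence and track them
#'
#' Connected induced k-subgraphs are enumerated on the union adjacency graph
#' (a superset of every frame's groups), then each group's per-frame
#' connectivity and topology class are evaluated by vectorised mask lookups.
#' The result is equivalent to merging per-frame enumerations: a group is a
#' candidate iff it is connected in at least one frame.
#'
#' @param seq a `tissue_sequence`.
#' @param k group size (2..6 supported for topology classes).
#' @return an object of class `group_tracks`: list with `k`, `members`
#'   (n x k id matrix), `keys`, `present`, `connected` (frames x n logical),
#'   `class_mask` (frames x n integer; NA where not fully present),
#'   `first_frame`, `last_frame`.
#' @export
track_groups <- function(seq, k) {
  frames <- seq$frames
  nf <- length(frames)
  ids <- sort(unique(unlist(lapply(frames, frame_cell_ids))))
  nid <- length(ids)
  # union adjacency
  U <- matrix(FALSE, nid, nid, dimnames = list(ids, ids))
  adjm <- vector("list", nf)
  for (f in seq_len(nf)) {
    p <- frame_adjacency_pairs(frames[[f]])
    i <- match(p[, 1L], ids); j <- match(p[, 2L], ids)
    M <- matrix(FALSE, nid, nid)
    M[cbind(i, j)] <- TRUE; M[cbind(j, i)] <- TRUE
    adjm[[f]] <- M
    U <- U | M
  }
  G <- connected_induced_subgraphs(U, k)
  n_g <- nrow(G)
  idx <- matrix(match(G, ids), n_g, k)
  slots <- pair_slots(k)
  w <- 2^(seq_len(nrow(slots)) - 1L)
  conn_tab <- connectivity_table(k)
  present <- matrix(FALSE, nf, n_g)
  connected <- matrix(FALSE, nf, n_g)
  class_mask <- matrix(NA_integer_, nf, n_g)
  pres_id <- vapply(frames, function(f) ids %in% frame_cell_ids(f), logical(nid))
  for (f in seq_len(nf)) {
    M <- adjm[[f]]
    pr <- matrix(pres_id[, f][idx], n_g, k)
    present[f, ] <- rowSums(pr) == k
    mask <- integer(n_g)
    for (s in seq_len(nrow(slots))) {
      a <- idx[, slots[s, 1L]]; b <- idx[, slots[s, 2L]]
      mask <- mask + w[s] * M[cbind(a, b)]
    }
    class_mask[f, present[f, ]] <- mask[present[f, ]]
    connected[f, ] <- present[f, ] & conn_tab[mask + 1L]
  }
  keep <- colSums(connected) > 0L
  G <- G[keep, , drop = FALSE]
  present <- present[, keep, drop = FALSE]
  connected <- connected[, keep, drop = FALSE]
  class_mask <- class_mask[, keep, drop = FALSE]
  first_frame <- apply(present, 2L, function(x) which(x)[1L])
  last_frame <- apply(present, 2L, function(x) rev(which(x))[1L])
  structure(list(
    k = k,
    members = G,
    keys = apply(G, 1L, paste, collapse = "+"),
    present = present,
    connected = connected,
    class_mask = class_mask,
    first_frame = first_frame,
    last_frame = last_frame
  ), class = "group_tracks")
}

#' @export
print.group_tracks <- function(x, ...) {
  cat(sprintf("<group_tracks> %d groups of %d cells over %d frames\n",
              nrow(x$members), x$k, nrow(x$present)))
  invisible(x)
}

#' Per-frame topology class ids of one tracked group
#'
#' @param tracks a `group_tracks` object.
#' @param i group index.
#' @return character vector (NA where the group is not fully present).
#' @export
track_class_ids <- function(tracks, i) {
  k <- tracks$k
  vapply(tracks$class_mask[, i], function(m) {
    if (is.na(m)) NA_character_ else sprintf("k%d-c%d", k, canonical_mask(m, k))
  }, character(1))
}

# Subset a group_tracks object by group index.
tracks_subset <- function(tracks, idx) {
  structure(list(
    k = tracks$k,
    members = tracks$members[idx, , drop = FALSE],
    keys = tracks$keys[idx],
    present = tracks$present[, idx, drop = FALSE],
    connected = tracks$connected[, idx, drop = FALSE],
    class_mask = tracks$class_mask[, idx, drop = FALSE],
    first_frame = tracks$first_frame[idx],
    last_frame = tracks$last_frame[idx]
  ), class = "group_tracks")
}
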