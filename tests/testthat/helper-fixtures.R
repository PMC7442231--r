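# Shared fixtures and independent oracles.  Everything is generated in code;
# expensive simulations are memoised so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# A 6x6-cell tissue with one scripted T1 on an interior junction.
get_t1_sim <- function() {
  if (is.null(.fixtures$t1_sim)) {
    cfg <- sim_config(rows = 6, cols = 6, n_frames = 25, seed = 2,
                      scripted_events = list(script_t1(15L, 16L, 4L)))
    .fixtures$t1_sim <- simulate_tissue(cfg)
  }
  .fixtures$t1_sim
}

# Event-free relaxation of the same lattice.
get_quiet_sim <- function() {
  if (is.null(.fixtures$quiet_sim)) {
    cfg <- sim_config(rows = 5, cols = 5, n_frames = 6, seed = 1)
    .fixtures$quiet_sim <- simulate_tissue(cfg)
  }
  .fixtures$quiet_sim
}

# 5-cell rosette with staggered junction contraction.
get_rosette_sim <- function() {
  if (is.null(.fixtures$rosette_sim)) {
    cfg <- sim_config(rows = 6, cols = 6, n_frames = 32, seed = 4,
                      scripted_events = list(
                        script_rosette(list(c(15L, 16L), c(15L, 10L)),
                                       onset_frame = 4L, stagger_frames = 3L)))
    .fixtures$rosette_sim <- simulate_tissue(cfg)
  }
  .fixtures$rosette_sim
}

get_t1_template <- function() {
  if (is.null(.fixtures$t1_template)) {
    .fixtures$t1_template <- t1_template_from_simulation(seed = 990)
  }
  .fixtures$t1_template
}

# 3x3 toy tissue of 9 square 5x5-pixel cells separated by 1-pixel membrane.
toy_label_grid <- function() {
  L <- matrix(0L, 17, 17)
  for (i in 0:2) for (j in 0:2) {
    L[(i * 6 + 1):(i * 6 + 5), (j * 6 + 1):(j * 6 + 5)] <- i * 3L + j + 1L
  }
  L
}

# Hand-built frame: a ring of n cells around a centre cell (id n + 1), all
# pairwise adjacencies explicit.  Cell polygons are small squares placed on a
# circle; geometry only matters for tests that do not measure distances.
ring_frame <- function(n = 6, with_center_edges = TRUE) {
  mk_cell <- function(id, cx, cy, bnd) {
    list(id = id,
         boundary = cbind(cx + c(-0.4, 0.4, 0.4, -0.4),
                          cy + c(-0.4, -0.4, 0.4, 0.4)),
         is_boundary_cell = bnd)
  }
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cells <- c(lapply(seq_len(n), function(i) {
    mk_cell(i, cos(ang[i]), sin(ang[i]), TRUE)
  }), list(mk_cell(n + 1L, 0, 0, FALSE)))
  seg <- rbind(c(0, 0), c(1, 1))
  edges <- lapply(seq_len(n), function(i) {
    list(cells = c(i, i %% n + 1L), polyline = seg)
  })
  if (with_center_edges) {
    edges <- c(edges, lapply(seq_len(n), function(i) {
      list(cells = c(i, n + 1L), polyline = seg)
    }))
  }
  epi_frame(cells, edges, 0)
}

# Frame with given adjacency pair list and boundary flags, for graph-only
# operations.
adjacency_frame <- function(pairs, n_cells, boundary_ids = integer(0)) {
  cells <- lapply(seq_len(n_cells), function(i) {
    list(id = i, boundary = cbind(c(0, 1, 1, 0) + i * 2, c(0, 0, 1, 1)),
         is_boundary_cell = i %in% boundary_ids)
  })
  seg <- rbind(c(0, 0), c(1, 1))
  edges <- lapply(seq_len(nrow(pairs)), function(r) {
    list(cells = pairs[r, ], polyline = seg)
  })
  epi_frame(cells, edges, 0)
}

# ---------------------------------------------------------------------------
# Independent oracles

# Power-set enumeration of connected induced k-subgraphs.
brute_subgraphs <- function(A, k) {
  ids <- as.integer(rownames(A))
  n <- length(ids)
  if (k > n) return(matrix(integer(0), 0, k))
  if (k == 1L) return(matrix(sort(ids), ncol = 1L))
  combs <- utils::combn(n, k)
  conn <- function(S) {
    B <- A[S, S, drop = FALSE]
    seen <- logical(k); seen[1L] <- TRUE
    repeat {
      r <- seen | (colSums(B & seen) > 0)
      if (identical(r, seen)) break
      seen <- r
    }
    all(seen)
  }
  keep <- apply(combs, 2L, conn)
  if (!any(keep)) return(matrix(integer(0), 0, k))
  m <- t(apply(combs[, keep, drop = FALSE], 2L, function(s) sort(ids[s])))
  m[do.call(order, split(m, col(m))), , drop = FALSE]
}

# Exhaustive min-cost monotone path with the repetition cap (DTW oracle).
brute_dtw <- function(cost, max_repeat) {
  m <- nrow(cost); n <- ncol(cost)
  best <- Inf
  rec <- function(i, j, acc, runv, runh) {
    acc <- acc + cost[i, j]
    if (acc >= best) return()
    if (i == m && j == n) { best <<- min(best, acc); return() }
    if (i < m && j < n) rec(i + 1L, j + 1L, acc, 0L, 0L)
    if (i < m && runv < max_repeat - 1L) rec(i + 1L, j, acc, runv + 1L, 0L)
    if (j < n && runh < max_repeat - 1L) rec(i, j + 1L, acc, 0L, runh + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  best
}

cost_of <- function(TV, SV) {
  as.matrix(stats::dist(rbind(TV, SV)))[seq_len(nrow(TV)),
                                        nrow(TV) + seq_len(nrow(SV)),
                                        drop = FALSE]
}

# Geometric enclosure oracle: rasterise member polygons onto a grid and
# flood-fill the outside; a non-member cell is enclosed iff its centroid
# pixel cannot be reached from the raster border.
geometric_enclosure_oracle <- function(members, frame, res = 80L) {
  polys <- lapply(frame$cells[as.character(members)], function(cl) cl$boundary)
  allb <- do.call(rbind, lapply(frame$cells, function(cl) cl$boundary))
  x0 <- min(allb[, 1L]) - 1; x1 <- max(allb[, 1L]) + 1
  y0 <- min(allb[, 2L]) - 1; y1 <- max(allb[, 2L]) + 1
  xs <- seq(x0, x1, length.out = res)
  ys <- seq(y0, y1, length.out = res)
  blocked <- matrix(FALSE, res, res)
  for (p in polys) {
    for (r in seq_len(res)) for (c in seq_len(res)) {
      if (!blocked[r, c] && point_in_polygon(c(xs[c], ys[r]), p)) {
        blocked[r, c] <- TRUE
      }
    }
  }
  reach <- matrix(FALSE, res, res)
  queue <- unique(c(
    which(!blocked[1L, ]) * res - res + 1L,   # row 1
    which(!blocked[res, ]) * res - res + res, # row res
    which(!blocked[, 1L]),                    # col 1
    (res - 1L) * res + which(!blocked[, res])
  ))
  reach[queue] <- TRUE
  queue <- as.list(queue)
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    r <- (p - 1L) %% res + 1L; c <- (p - 1L) %/% res + 1L
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + o[1L]; c2 <- c + o[2L]
      if (r2 < 1L || r2 > res || c2 < 1L || c2 > res) next
      p2 <- (c2 - 1L) * res + r2
      if (!blocked[p2] && !reach[p2]) {
        reach[p2] <- TRUE
        queue <- c(queue, p2)
      }
    }
  }
  others <- setdiff(frame_cell_ids(frame), members)
  for (id in others) {
    cen <- colMeans(frame$cells[[as.character(id)]]$boundary)
    r <- which.min(abs(ys - cen[2L])); c <- which.min(abs(xs - cen[1L]))
    if (!reach[r, c]) return(TRUE)
  }
  FALSE
}

# Junction length of a cell pair across frames (0 when not adjacent).
junction_length_series <- function(seq, a, b) {
  vapply(seq$frames, function(fr) {
    e <- frame_edge_between(fr, a, b)
    if (is.null(e)) 0 else polyline_length(e$polyline)
  }, numeric(1))
}
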