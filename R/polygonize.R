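# Conversion of tracked label images into the polygonised tissue
# representation, overlap-based index propagation, and rasterisation of
# simulated tissues back into label images.
#
# Raster convention: labels[row, col] with row = y (downward), col = x
# (rightward); pixel centres sit at 0-based integer coordinates, converted to
# micrometres via pixel_size.  Label 0 is membrane/background; every positive
# label is one 4-connected cell region separated from its neighbours by a
# 1-pixel membrane skeleton.

.shift_mat <- function(M, dr, dc, fill = FALSE) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc, drop = FALSE]
  out
}

.count_neighbors <- function(mask, conn = 8L) {
  offs <- if (conn == 8L) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (o in offs) acc <- acc + .shift_mat(mask, o[1L], o[2L])
  acc
}

# Connected components of a logical mask (BFS); returns integer matrix, 0 in
# background.
.components <- function(mask, conn = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  offs <- if (conn == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1L]; c2 <- cc + offs[k, 2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        p2 <- (c2 - 1L) * nr + r2
        if (mask[p2] && comp[p2] == 0L) {
          comp[p2] <- cur
          queue <- c(queue, p2)
        }
      }
    }
  }
  comp
}

# Moore-neighbour boundary trace of a 4-connected region mask; returns the
# ordered boundary pixel centres (row, col), clockwise.
.region_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  start <- idx[1L]  # first in column-major order: topmost of leftmost column
  r0 <- (start - 1L) %% nr + 1L; c0 <- (start - 1L) %/% nr + 1L
  # Moore neighbourhood in clockwise order starting from W
  moore <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(-1, -1, 0, 1, 1, 1, 0, -1))
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  contour <- matrix(c(r0, c0), 1L, 2L)
  # backtrack starts pointing W
  b <- 1L
  r <- r0; cc <- c0
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (step in seq_len(8L)) {
      k <- ((b - 1L + step - 1L) %% 8L) + 1L
      r2 <- r + moore[k, 1L]; c2 <- cc + moore[k, 2L]
      if (inside(r2, c2)) {
        # new backtrack: neighbour index just before k
        b <- ((k - 2L) %% 8L) + 1L
        if (r2 == r0 && c2 == c0 && !is.na(first_dir) && nrow(contour) > 2L) {
          return(contour)
        }
        if (is.na(first_dir)) first_dir <- k
        r <- r2; cc <- c2
        contour <- rbind(contour, c(r, cc))
        found <- TRUE
        break
      }
    }
    if (!found) return(contour)  # isolated pixel
    if (nrow(contour) > 4L * (nr * nc)) return(contour)  # safety
  }
}

# A membrane is non-skeletal when some "deep" 0-pixel (one with no positive
# neighbour) lies tightly between two distinct cell labels along one axis:
# that rules out open background wedges at the tissue rim, where cells sit to
# one side only or farther away.
.needs_thinning <- function(L, reach = 2L) {
  nr <- nrow(L); nc <- ncol(L)
  pos <- L > 0L
  deep <- which((L == 0L) & (.count_neighbors(pos, 8L) == 0L))
  axes <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  first_label <- function(r, cc, dr, dc) {
    for (s in seq_len(reach)) {
      r2 <- r + s * dr; c2 <- cc + s * dc
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) return(0L)
      if (L[r2, c2] > 0L) return(L[r2, c2])
    }
    0L
  }
  for (p in deep) {
    r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
    for (ax in axes) {
      a <- first_label(r, cc, ax[1L], ax[2L])
      if (a == 0L) next
      b <- first_label(r, cc, -ax[1L], -ax[2L])
      if (b > 0L && a != b) return(TRUE)
    }
  }
  FALSE
}

# Grow cell regions into thick membrane blobs until no deep 0-pixel remains;
# regions stay separated by a 1-2 pixel membrane.
.thin_membrane <- function(L) {
  nr <- nrow(L)
  repeat {
    pos <- L > 0L
    deep <- (L == 0L) & (.count_neighbors(pos, 8L) == 0L)
    if (!any(deep)) break
    cand <- which((L == 0L) & (.count_neighbors(pos, 4L) > 0L) &
                    (.count_neighbors(deep, 8L) > 0L))
    if (!length(cand)) break
    snapshot <- L
    nc <- ncol(L)
    for (p in cand) {
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + o[1L]; c2 <- cc + o[2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (snapshot[r2, c2] > 0L) {
          L[r, cc] <- snapshot[r2, c2]
          break
        }
      }
    }
  }
  L
}

#' Polygonise a label frame
#'
#' Converts a tracked label image (cells separated by a 1-pixel membrane
#' skeleton) into cell polygons, junction polylines and the adjacency
#' relation.  Tissue vertices are detected as branch points of the membrane
#' skeleton (membrane pixels with three or more membrane neighbours in
#' 8-connectivity; clusters merged at their centroid); each junction becomes
#' the chain of membrane pixel centres between two vertices, simplified by
#' Douglas-Peucker with the given tolerance.  Two cells are adjacent iff they
#' share a junction chain; meeting at a single branch point does not qualify.
#'
#' @param labels integer matrix (0 = membrane/background).
#' @param pixel_size pixel edge length in micrometres.
#' @param simplify_tol Douglas-Peucker tolerance in pixels (default 1).
#' @param time frame acquisition time in seconds.
#' @return an `epi_frame`; cell polygons are in micrometres.
#' @export
polygonize_frame <- function(labels, pixel_size = 0.2405, simplify_tol = 1,
                             time = 0) {
  L <- labels
  if (nrow(L) < 3L || ncol(L) < 3L) stop("raster must be at least 3 x 3")
  if (!any(L > 0)) stop("empty frame: raster has no positive labels")
  nr <- nrow(L); nc <- ncol(L)
  pos <- L > 0
  if (.needs_thinning(L)) {
    warning("membrane is not a 1-pixel skeleton; thinning applied")
    L <- .thin_membrane(L)
    pos <- L > 0
  }
  wall <- (L == 0L) & (.count_neighbors(pos, 8L) > 0L)
  branch <- wall & (.count_neighbors(wall, 8L) >= 3L)
  bcomp <- .components(branch, 8L)
  n_bc <- max(bcomp)
  # vertex centroids (micrometres; x = col-1, y = row-1)
  vpos <- matrix(NA_real_, n_bc, 2L)
  for (b in seq_len(n_bc)) {
    px <- which(bcomp == b)
    rr <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
    vpos[b, ] <- c(mean(cc - 1L), mean(rr - 1L)) * pixel_size
  }
  chain_mask <- wall & !branch
  ccomp <- .components(chain_mask, 8L)
  n_ch <- max(ccomp)
  offs8 <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  offs4 <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nbrs_of <- function(r, c, offs) {
    r2 <- r + offs[, 1L]; c2 <- c + offs[, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    cbind(r2[ok], c2[ok])
  }
  chains <- list()
  for (ch in seq_len(n_ch)) {
    px <- which(ccomp == ch)
    rr <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
    n_px <- length(px)
    # order pixels by walking from an endpoint (<= 1 in-chain neighbour)
    inchain <- matrix(FALSE, nr, nc); inchain[px] <- TRUE
    deg <- vapply(seq_len(n_px), function(i) {
      nb <- nbrs_of(rr[i], cc[i], offs8)
      sum(inchain[nb])
    }, integer(1))
    start <- if (any(deg <= 1L)) which(deg <= 1L)[1L] else 1L
    ordr <- integer(n_px)
    used <- logical(n_px)
    ordr[1L] <- start; used[start] <- TRUE
    key <- paste(rr, cc)
    for (s in seq_len(n_px - 1L)) {
      r <- rr[ordr[s]]; c <- cc[ordr[s]]
      # prefer 4-neighbours for clean ordering
      nb4 <- nbrs_of(r, c, offs4); nb8 <- nbrs_of(r, c, offs8)
      cand <- c(match(paste(nb4[, 1L], nb4[, 2L]), key),
                match(paste(nb8[, 1L], nb8[, 2L]), key))
      cand <- cand[!is.na(cand)]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      ordr[s + 1L] <- cand[1L]; used[cand[1L]] <- TRUE
    }
    ordr <- ordr[ordr > 0L]
    rr <- rr[ordr]; cc <- cc[ordr]
    # flanking cell labels (4-neighbours of chain pixels)
    flank <- integer(0)
    for (i in seq_along(rr)) {
      nb <- nbrs_of(rr[i], cc[i], offs4)
      flank <- c(flank, L[nb][L[nb] > 0L])
    }
    tab <- sort(table(flank), decreasing = TRUE)
    cells <- as.integer(names(tab))[seq_len(min(2L, length(tab)))]
    # attach endpoint vertices (branch-cluster centroids) or border terminals
    endpt_vertex <- function(i) {
      nb <- nbrs_of(rr[i], cc[i], offs8)
      bs <- unique(bcomp[nb][bcomp[nb] > 0L])
      if (length(bs)) vpos[bs[1L], ] else NULL
    }
    pts <- cbind(cc - 1L, rr - 1L) * pixel_size
    v1 <- endpt_vertex(1L); v2 <- endpt_vertex(length(rr))
    poly <- rbind(if (!is.null(v1)) v1, pts, if (!is.null(v2)) v2)
    poly <- dp_simplify(poly, simplify_tol * pixel_size)
    chains[[ch]] <- list(cells = sort(cells), polyline = poly,
                         n_flank = length(tab))
  }
  # cells: regions of positive labels
  ids <- sort(unique(L[pos]))
  touches_border <- vapply(ids, function(id) {
    m <- L == id
    any(m[1L, ]) || any(m[nr, ]) || any(m[, 1L]) || any(m[, nc])
  }, logical(1))
  cellpolys <- .assemble_cell_polygons(L, ids, chains, pixel_size, nr, nc)
  cells <- lapply(seq_along(ids), function(i) {
    list(id = ids[i], boundary = cellpolys[[i]],
         is_boundary_cell = touches_border[i])
  })
  names(cells) <- ids
  edges <- Filter(function(ch) length(ch$cells) == 2L, chains)
  edges <- lapply(edges, function(ch) list(cells = ch$cells,
                                           polyline = ch$polyline))
  epi_frame(cells, edges, time = time)
}

# Assemble each cell's boundary polygon by chaining its incident junction
# polylines end-to-end; cells whose chain walk does not close (typically
# border cells) fall back to the pixel-region contour.
.assemble_cell_polygons <- function(L, ids, chains, pixel_size, nr, nc) {
  by_cell <- lapply(ids, function(id) {
    which(vapply(chains, function(ch) id %in% ch$cells, logical(1)))
  })
  lapply(seq_along(ids), function(i) {
    idx <- by_cell[[i]]
    poly <- NULL
    if (length(idx) >= 2L) {
      poly <- .walk_chain_cycle(lapply(chains[idx], function(ch) ch$polyline))
    }
    if (is.null(poly)) {
      ct <- .region_contour(L == ids[i])
      poly <- cbind(ct[, 2L] - 1L, ct[, 1L] - 1L) * pixel_size
    }
    poly
  })
}

# Try to order polylines into one closed cycle by matching endpoints.
.walk_chain_cycle <- function(polys) {
  n <- length(polys)
  keyf <- function(p) sprintf("%.3f_%.3f", p[1L], p[2L])
  ends <- lapply(polys, function(pl) list(a = pl[1L, ], b = pl[nrow(pl), ]))
  used <- logical(n)
  out <- polys[[1L]]
  used[1L] <- TRUE
  target <- keyf(ends[[1L]]$a)
  cur <- keyf(ends[[1L]]$b)
  for (step in seq_len(n - 1L)) {
    nxt <- 0L; flip <- FALSE
    for (j in which(!used)) {
      if (keyf(ends[[j]]$a) == cur) { nxt <- j; flip <- FALSE; break }
      if (keyf(ends[[j]]$b) == cur) { nxt <- j; flip <- TRUE; break }
    }
    if (nxt == 0L) return(NULL)
    pl <- polys[[nxt]]
    if (flip) pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
    out <- rbind(out, pl[-1L, , drop = FALSE])
    used[nxt] <- TRUE
    cur <- keyf(pl[nrow(pl), ])
  }
  if (cur != target || !all(used)) return(NULL)
  out[-nrow(out), , drop = FALSE]
}

#' Junction length
#'
#' Sum of the lengths of the straight segments assembling a junction
#' polyline.
#'
#' @param edge an edge element (list with `polyline`).
#' @return length in micrometres.
#' @export
edge_length <- function(edge) polyline_length(edge$polyline)

#' Propagate cell indices between consecutive registered frames
#'
#' A next-frame cell inherits the index of the previous-frame cell whose
#' mutual overlap exceeds half the area of both cells; all other cells are
#' treated as new entries and receive `max(all indices) + 1`.
#'
#' @param prev integer label matrix with established indices.
#' @param next_ integer label matrix spatially registered to `prev` (its
#'   labels are arbitrary and will be replaced).
#' @return relabelled version of `next_`.
#' @export
propagate_indices <- function(prev, next_) {
  if (!identical(dim(prev), dim(next_))) stop("frames must share dimensions")
  both <- prev > 0L & next_ > 0L
  ov <- table(prev = prev[both], nxt = next_[both])
  area_prev <- table(prev[prev > 0L])
  area_next <- table(next_[next_ > 0L])
  next_ids <- sort(as.integer(names(area_next)))
  max_idx <- max(prev)
  mapping <- integer(0)
  claimed <- integer(0)
  for (id in next_ids) {
    col <- as.character(id)
    newlab <- NA_integer_
    if (col %in% colnames(ov)) {
      counts <- ov[, col]
      cand <- names(counts)[counts > 0.5 * area_next[[col]] &
                            counts > 0.5 * area_prev[names(counts)]]
      if (length(cand) > 1L) stop("tracking conflict: multiple parents")
      if (length(cand) == 1L) {
        if (as.integer(cand) %in% claimed) {
          stop("tracking conflict: index ", cand, " claimed twice")
        }
        newlab <- as.integer(cand)
        claimed <- c(claimed, newlab)
      }
    }
    if (is.na(newlab)) {
      max_idx <- max_idx + 1L
      newlab <- max_idx
    }
    mapping[as.character(id)] <- newlab
  }
  out <- next_
  out[next_ > 0L] <- mapping[as.character(next_[next_ > 0L])]
  out
}

#' Rasterise a polygonised frame (or sequence) into label images
#'
#' Pixels take the label of the cell containing their centre; membrane is
#' drawn by clearing, for every 4-adjacent pair of differing positive
#' labels, the pixel with the larger label, which leaves a 1-pixel skeleton
#' separating all cell regions.
#'
#' @param x an `epi_frame` or `tissue_sequence`.
#' @param pixel_size pixel edge length in micrometres.
#' @return an integer label matrix, or a list of them for a sequence (all
#'   sharing one raster extent).
#' @export
render_labels <- function(x, pixel_size = 0.2405) {
  if (inherits(x, "tissue_sequence")) {
    ext <- .render_extent(x$frames, pixel_size)
    return(lapply(x$frames, .render_frame, pixel_size = pixel_size, ext = ext))
  }
  .render_frame(x, pixel_size, .render_extent(list(x), pixel_size))
}

.render_extent <- function(frames, pixel_size) {
  allb <- do.call(rbind, unlist(lapply(frames, function(fr) {
    lapply(fr$cells, function(cl) cl$boundary)
  }), recursive = FALSE))
  x0 <- min(allb[, 1L]); y0 <- min(allb[, 2L])
  nc <- ceiling((max(allb[, 1L]) - x0) / pixel_size) + 1L
  nr <- ceiling((max(allb[, 2L]) - y0) / pixel_size) + 1L
  list(x0 = x0, y0 = y0, nr = nr, nc = nc)
}

.render_frame <- function(frame, pixel_size, ext) {
  nr <- ext$nr; nc <- ext$nc
  M <- matrix(0L, nr, nc)
  xs <- ext$x0 + (seq_len(nc) - 1L) * pixel_size
  ys <- ext$y0 + (seq_len(nr) - 1L) * pixel_size
  for (cl in frame$cells) {
    b <- cl$boundary
    ry <- range(b[, 2L])
    rows <- which(ys >= ry[1L] - pixel_size & ys <= ry[2L] + pixel_size)
    nb <- nrow(b)
    j <- c(2:nb, 1L)
    for (r in rows) {
      y <- ys[r]
      crosses <- (b[, 2L] > y) != (b[j, 2L] > y)
      if (!any(crosses)) next
      xi <- b[crosses, 1L] + (y - b[crosses, 2L]) /
        (b[j, 2L][crosses] - b[crosses, 2L]) * (b[j, 1L][crosses] - b[crosses, 1L])
      xi <- sort(xi)
      for (p in seq(1L, length(xi) - 1L, by = 2L)) {
        cols <- which(xs >= xi[p] & xs <= xi[p + 1L])
        M[r, cols] <- cl$id
      }
    }
  }
  # membrane: clear the larger label of any 4-adjacent differing positive pair
  for (o in list(c(0, 1), c(1, 0))) {
    nb <- .shift_mat(M, o[1L], o[2L], fill = 0L)
    d1 <- M > 0L & nb > 0L & nb != M
    M[d1 & M > nb] <- 0L
    nb2 <- .shift_mat(M, -o[1L], -o[2L], fill = 0L)
    d2 <- M > 0L & nb2 > 0L & nb2 != M
    M[d2 & M > nb2] <- 0L
  }
  M
}
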