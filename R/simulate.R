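# Vertex-model simulator of a planar epithelium.
#
# The tissue is a polygonal tiling: vertices carry positions, cells are
# counter-clockwise vertex cycles, junctions are vertex pairs shared by two
# cells.  The mechanical energy is the standard area-elasticity /
# perimeter-contractility / line-tension form
#
#   E = sum_cells [ K/2 (A - A0)^2 + G/2 P^2 ] + sum_edges lambda_e * l_e
#
# relaxed by overdamped gradient descent with an adaptive step and pinned
# outer-boundary vertices.  Scripted events raise the tension of chosen
# junctions to drive T1 swaps, abortive (reversing) contractions, rosettes
# and rosette hubs; every scripted event is emitted as a ground-truth record
# so detection can be scored against it.

#' Simulation configuration
#'
#' @param rows,cols size of the initial hexagonal lattice (cells).
#' @param edge_len target hexagon edge length (micrometres).  The default of
#'   3 um gives cells roughly 6 um across, typical of a germband epithelium.
#' @param K area elastic modulus.
#' @param gamma perimeter contractility.
#' @param lambda_base baseline junction line tension.
#' @param lambda_high elevated tension applied to scripted contracting
#'   junctions.
#' @param lambda_grow tension applied to a newly formed junction while it
#'   establishes itself (negative values favour growth).
#' @param lambda_stab tension retained on matured new junctions for the rest
#'   of the run, representing junction stabilisation; without it the swapped
#'   configuration would relax back towards the four-way vertex.
#' @param t1_swap_threshold junction length (um) below which a scripted
#'   contraction collapses into a higher-order vertex.
#' @param jitter_sd s.d. of the seeded vertex jitter applied to the initial
#'   lattice (um).
#' @param n_relax gradient-descent steps run between consecutive frames.
#' @param frame_interval_s time between emitted frames (seconds).
#' @param n_frames number of frames to emit.
#' @param pixel_size raster pixel size used when rendering (um).
#' @param grow_frames frames during which a new junction keeps `lambda_grow`.
#' @param scripted_events list of event descriptions; see
#'   [script_t1()], [script_reversal()], [script_rosette()], [script_hub()],
#'   [script_pulse()], [script_dilation()].
#' @param seed integer seed fixing all randomness of the run.
#' @return a `sim_config` list.
#' @export
sim_config <- function(rows = 8, cols = 8, edge_len = 3,
                       K = 0.02, gamma = 0.01, lambda_base = 0.05,
                       lambda_high = 0.45, lambda_grow = -0.35,
                       lambda_stab = -0.3,
                       t1_swap_threshold = 0.3,
                       jitter_sd = 0.25, n_relax = 15,
                       frame_interval_s = 30, n_frames = 40,
                       pixel_size = 0.2405, grow_frames = 8,
                       scripted_events = list(), seed = 1) {
  stopifnot(K >= 0, gamma >= 0, t1_swap_threshold > 0, n_frames >= 1)
  structure(list(
    rows = rows, cols = cols, edge_len = edge_len, K = K, gamma = gamma,
    lambda_base = lambda_base, lambda_high = lambda_high,
    lambda_grow = lambda_grow, lambda_stab = lambda_stab,
    t1_swap_threshold = t1_swap_threshold,
    jitter_sd = jitter_sd, n_relax = n_relax,
    frame_interval_s = frame_interval_s, n_frames = n_frames,
    pixel_size = pixel_size, grow_frames = grow_frames,
    scripted_events = scripted_events, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Script a T1 neighbour exchange
#'
#' Elevates tension on the junction between cells `a` and `b` from
#' `onset_frame` until the junction collapses; the four-way vertex is held for
#' one frame and then resolved so that the orthogonal cell pair gains a
#' junction.
#'
#' @param a,b cell ids of the junction to contract (must be adjacent).
#' @param onset_frame frame at which the tension programme starts.
#' @return event description list.
#' @export
script_t1 <- function(a, b, onset_frame) {
  list(type = "t1", pair = c(a, b), onset_frame = onset_frame)
}

#' Script a reversing (abortive) T1
#'
#' The junction contracts under elevated tension down to `release_frac` of
#' its onset length and is then released, recovering without any neighbour
#' exchange.
#'
#' @inheritParams script_t1
#' @param release_frac fraction of the onset length at which tension is
#'   released (kept well above the swap threshold).
#' @export
script_reversal <- function(a, b, onset_frame, release_frac = 0.35) {
  list(type = "t1_reversal", pair = c(a, b), onset_frame = onset_frame,
       release_frac = release_frac)
}

#' Script a multicellular rosette
#'
#' Contracts the junctions listed in `pairs` (2 junctions for a 5-cell
#' rosette, 3 for a 6-cell one), optionally staggered, until all participating
#' cells meet at a single vertex; after `hold_frames` the rosette is resolved
#' by a vertex split.
#'
#' @param pairs list of cell-id pairs, each an existing junction; consecutive
#'   junctions must share a vertex.
#' @param onset_frame frame of the first contraction.
#' @param stagger_frames onset delay between consecutive junctions.
#' @param hold_frames frames during which the single-vertex state is held.
#' @export
script_rosette <- function(pairs, onset_frame, stagger_frames = 0,
                           hold_frames = 1, lambda = NULL) {
  list(type = "rosette", pairs = pairs, onset_frame = onset_frame,
       stagger_frames = stagger_frames, hold_frames = hold_frames,
       lambda = lambda)
}

#' Script a rosette hub
#'
#' Builds a 5-cell rosette, then at the persistent core vertex releases one
#' member and recruits a new one while at least four cells keep surrounding
#' the vertex.
#'
#' @inheritParams script_rosette
#' @export
script_hub <- function(pairs, onset_frame, stagger_frames = 0,
                       lambda = NULL) {
  list(type = "hub", pairs = pairs, onset_frame = onset_frame,
       stagger_frames = stagger_frames, lambda = lambda)
}

#' Script a pulsatile junction contraction (distractor)
#'
#' Tension is elevated and then released well before the swap threshold, so
#' the junction shortens moderately and recovers; no topological change ever
#' occurs.  These act as distractor deformations in validation corpora.
#'
#' @inheritParams script_reversal
#' @export
script_pulse <- function(a, b, onset_frame, release_frac = 0.6) {
  list(type = "pulse", pair = c(a, b), onset_frame = onset_frame,
       release_frac = release_frac)
}

#' Script a transient cell-area change (distractor)
#'
#' The preferred area of one cell is inflated by `factor` for `duration`
#' frames and then restored, mimicking division-like area fluctuations.
#'
#' @param cell cell id.
#' @param onset_frame first affected frame.
#' @param factor multiplicative change of the preferred area.
#' @param duration number of affected frames.
#' @export
script_dilation <- function(cell, onset_frame, factor = 1.6, duration = 8) {
  list(type = "dilation", cell = cell, onset_frame = onset_frame,
       factor = factor, duration = duration)
}

# ---------------------------------------------------------------------------
# Initial lattice

# Perturbed hexagonal lattice.  Returns a sim state: V (vertex positions),
# cells (named list of ccw vertex cycles), pinned (logical per vertex), A0.
hex_lattice <- function(rows, cols, s, jitter_sd) {
  key_of <- function(x, y) sprintf("%.4f_%.4f", x, y)
  vkeys <- character(0)
  vx <- numeric(0); vy <- numeric(0)
  cells <- list()
  dx <- sqrt(3) * s
  ang <- (seq_len(6) * 60 - 30) * pi / 180  # pointy-top hexagon corners
  cid <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      cx <- c * dx + (r %% 2) * dx / 2
      cy <- r * 1.5 * s
      cyc <- integer(6)
      for (i in seq_len(6)) {
        x <- cx + s * cos(ang[i]); y <- cy + s * sin(ang[i])
        k <- key_of(x, y)
        idx <- match(k, vkeys)
        if (is.na(idx)) {
          vkeys <- c(vkeys, k); vx <- c(vx, x); vy <- c(vy, y)
          idx <- length(vkeys)
        }
        cyc[i] <- idx
      }
      cid <- cid + 1L
      cells[[as.character(cid)]] <- cyc
    }
  }
  V <- cbind(vx, vy)
  dimnames(V) <- NULL
  # jitter interior vertices only (boundary stays a clean frame)
  st <- list(V = V, cells = cells)
  st$pinned <- boundary_vertices(st)
  jit <- matrix(stats::rnorm(2 * nrow(V), 0, jitter_sd), ncol = 2)
  jit[st$pinned, ] <- 0
  st$V <- V + jit
  st$A0 <- stats::setNames(rep(polygon_area(hex_corners(s)), length(cells)),
                           names(cells))
  # ensure counter-clockwise orientation (positive shoelace area)
  st$cells <- lapply(st$cells, function(cyc) {
    if (polygon_area(st$V[cyc, , drop = FALSE], signed = TRUE) < 0) rev(cyc) else cyc
  })
  st
}

hex_corners <- function(s) {
  ang <- (seq_len(6) * 60 - 30) * pi / 180
  cbind(s * cos(ang), s * sin(ang))
}

# Unique edges of a state: data.frame u, w (vertex ids, u < w), c1, c2
# (incident cell ids; c2 NA for tissue-rim edges).
state_edges <- function(st) {
  us <- integer(0); ws <- integer(0); owner <- integer(0)
  for (nm in names(st$cells)) {
    cyc <- st$cells[[nm]]
    n <- length(cyc)
    a <- cyc; b <- cyc[c(2:n, 1L)]
    us <- c(us, pmin(a, b)); ws <- c(ws, pmax(a, b))
    owner <- c(owner, rep(as.integer(nm), n))
  }
  key <- paste(us, ws)
  first <- !duplicated(key)
  idx2 <- match(key, key[first])
  c1 <- owner[first]
  c2 <- rep(NA_integer_, sum(first))
  dup <- which(duplicated(key))
  c2[idx2[dup]] <- owner[dup]
  data.frame(u = us[first], w = ws[first], c1 = c1, c2 = c2)
}

boundary_vertices <- function(st) {
  ed <- state_edges(st)
  rim <- ed[is.na(ed$c2), ]
  pinned <- logical(nrow(st$V))
  pinned[c(rim$u, rim$w)] <- TRUE
  pinned
}

# ---------------------------------------------------------------------------
# Mechanics

# Corner table for vectorised force evaluation.
corner_table <- function(st) {
  cell_i <- integer(0); v <- integer(0); p <- integer(0); nx <- integer(0)
  nms <- names(st$cells)
  for (i in seq_along(nms)) {
    cyc <- st$cells[[i]]
    n <- length(cyc)
    cell_i <- c(cell_i, rep(i, n))
    v <- c(v, cyc)
    p <- c(p, cyc[c(n, seq_len(n - 1L))])
    nx <- c(nx, cyc[c(2:n, 1L)])
  }
  list(cell = cell_i, v = v, p = p, nx = nx, n_cells = length(nms))
}

cell_areas <- function(st, ct) {
  x <- st$V[, 1L]; y <- st$V[, 2L]
  terms <- 0.5 * (x[ct$v] * y[ct$nx] - x[ct$nx] * y[ct$v])
  as.numeric(rowsum(terms, ct$cell))
}

cell_perims <- function(st, ct) {
  d <- sqrt((st$V[ct$nx, 1L] - st$V[ct$v, 1L])^2 +
            (st$V[ct$nx, 2L] - st$V[ct$v, 2L])^2)
  as.numeric(rowsum(d, ct$cell))
}

tissue_energy <- function(st, ct, ed, lambda, cfg, A0) {
  A <- cell_areas(st, ct)
  P <- cell_perims(st, ct)
  len <- sqrt((st$V[ed$w, 1L] - st$V[ed$u, 1L])^2 +
              (st$V[ed$w, 2L] - st$V[ed$u, 2L])^2)
  sum(cfg$K / 2 * (A - A0)^2) + sum(cfg$gamma / 2 * P^2) + sum(lambda * len)
}

tissue_forces <- function(st, ct, ed, lambda, cfg, A0) {
  x <- st$V[, 1L]; y <- st$V[, 2L]
  A <- cell_areas(st, ct)
  P <- cell_perims(st, ct)
  ka <- cfg$K * (A - A0)         # per cell
  gp <- cfg$gamma * P
  # area term: dA/dv = 0.5 * (y_n - y_p, x_p - x_n)
  fx <- -ka[ct$cell] * 0.5 * (y[ct$nx] - y[ct$p])
  fy <- -ka[ct$cell] * 0.5 * (x[ct$p] - x[ct$nx])
  # perimeter term: dP/dv = unit(v - p) + unit(v - nx)
  dpx <- x[ct$v] - x[ct$p]; dpy <- y[ct$v] - y[ct$p]
  lp <- pmax(sqrt(dpx^2 + dpy^2), 1e-12)
  dnx <- x[ct$v] - x[ct$nx]; dny <- y[ct$v] - y[ct$nx]
  ln <- pmax(sqrt(dnx^2 + dny^2), 1e-12)
  fx <- fx - gp[ct$cell] * (dpx / lp + dnx / ln)
  fy <- fy - gp[ct$cell] * (dpy / lp + dny / ln)
  Fv <- rowsum(cbind(fx, fy), ct$v)
  Fm <- matrix(0, nrow(st$V), 2L)
  Fm[as.integer(rownames(Fv)), ] <- Fv
  # line tension on unique edges
  ex <- x[ed$u] - x[ed$w]; ey <- y[ed$u] - y[ed$w]
  el <- pmax(sqrt(ex^2 + ey^2), 1e-12)
  gx <- lambda * ex / el; gy <- lambda * ey / el
  Fe <- rowsum(cbind(c(-gx, gx), c(-gy, gy)), c(ed$u, ed$w))
  Fm[as.integer(rownames(Fe)), ] <- Fm[as.integer(rownames(Fe)), ] + Fe
  Fm[st$pinned, ] <- 0
  Fm
}

# One block of adaptive gradient-descent steps; returns updated state and the
# step size reached.  Energy is non-increasing across accepted steps.
relax_steps <- function(st, ct, ed, lambda, cfg, A0, n_steps, eta) {
  E <- tissue_energy(st, ct, ed, lambda, cfg, A0)
  for (s in seq_len(n_steps)) {
    Fm <- tissue_forces(st, ct, ed, lambda, cfg, A0)
    accepted <- FALSE
    for (try in 1:25) {
      V2 <- st$V + eta * Fm
      st2 <- st; st2$V <- V2
      E2 <- tissue_energy(st2, ct, ed, lambda, cfg, A0)
      if (is.finite(E2) && E2 <= E + 1e-12) {
        st <- st2; E <- E2; eta <- min(eta * 1.2, 0.2); accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) stop("vertex-model relaxation failed to find a descent step")
  }
  list(st = st, eta = eta, energy = E)
}

# ---------------------------------------------------------------------------
# Topological moves

# Collapse the edge (u, w) into a single new vertex at its midpoint.
collapse_edge_vertices <- function(st, u, w) {
  m <- nrow(st$V) + 1L
  st$V <- rbind(st$V, (st$V[u, ] + st$V[w, ]) / 2)
  st$pinned <- c(st$pinned, st$pinned[u] || st$pinned[w])
  st$cells <- lapply(st$cells, function(cyc) {
    cyc[cyc == u | cyc == w] <- m
    # drop consecutive duplicates (cyclically)
    n <- length(cyc)
    keep <- cyc != cyc[c(2:n, 1L)]
    cyc[keep]
  })
  st
}

# Cells incident to vertex m, ordered counter-clockwise around it.
vertex_cell_ring <- function(st, m) {
  inc <- names(st$cells)[vapply(st$cells, function(cyc) m %in% cyc, logical(1))]
  cen <- t(vapply(inc, function(nm) {
    polygon_centroid(st$V[st$cells[[nm]], , drop = FALSE])
  }, numeric(2)))
  angs <- atan2(cen[, 2L] - st$V[m, 2L], cen[, 1L] - st$V[m, 1L])
  as.integer(inc[order(angs)])
}

# Split vertex m so that cells ca and cd (non-adjacent in the ring around m)
# gain a shared junction of length delta.  Cells on one arc keep one daughter
# vertex, cells on the other arc the second; ca and cd receive both.
split_vertex <- function(st, m, ca, cd, delta) {
  ring <- vertex_cell_ring(st, m)
  ia <- match(ca, ring); id <- match(cd, ring)
  if (is.na(ia) || is.na(id)) stop("gain cells not incident to the vertex")
  n <- length(ring)
  idxs <- seq_len(n)
  # arcs strictly between ca and cd, walking the ring in both directions
  walk <- function(from, to) {
    out <- integer(0); i <- from
    repeat {
      i <- if (i == n) 1L else i + 1L
      if (i == to) break
      out <- c(out, i)
    }
    out
  }
  arc1 <- ring[walk(ia, id)]
  arc2 <- ring[walk(id, ia)]
  if (!length(arc1) || !length(arc2)) {
    stop("gain cells are ring-adjacent; split would be degenerate")
  }
  cen_of <- function(ids) {
    rowMeans(vapply(as.character(ids), function(nm) {
      polygon_centroid(st$V[st$cells[[nm]], , drop = FALSE])
    }, numeric(2)))
  }
  u_dir <- cen_of(arc1) - st$V[m, ]
  w_dir <- cen_of(arc2) - st$V[m, ]
  unit <- function(v) v / max(sqrt(sum(v^2)), 1e-12)
  axis <- unit(unit(u_dir) - unit(w_dir))
  u <- nrow(st$V) + 1L; w <- nrow(st$V) + 2L
  st$V <- rbind(st$V, st$V[m, ] + delta / 2 * axis,
                      st$V[m, ] - delta / 2 * axis)
  st$pinned <- c(st$pinned, st$pinned[m], st$pinned[m])
  repl_one <- function(cyc, newv) { cyc[cyc == m] <- newv; cyc }
  for (nm in as.character(arc1)) st$cells[[nm]] <- repl_one(st$cells[[nm]], u)
  for (nm in as.character(arc2)) st$cells[[nm]] <- repl_one(st$cells[[nm]], w)
  for (nm in as.character(c(ca, cd))) {
    cyc <- st$cells[[nm]]
    pos <- which(cyc == m)
    ins1 <- append(cyc[-pos], c(u, w), after = pos - 1L)
    ins2 <- append(cyc[-pos], c(w, u), after = pos - 1L)
    a1 <- polygon_area(st$V[ins1, , drop = FALSE], signed = TRUE)
    a2 <- polygon_area(st$V[ins2, , drop = FALSE], signed = TRUE)
    st$cells[[nm]] <- if (a1 >= a2) ins1 else ins2
  }
  list(st = st, new_edge = c(u, w))
}

current_edge_of_pair <- function(ed, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  i <- which((pmin(ed$c1, ed$c2) == lo) & (pmax(ed$c1, ed$c2) == hi))
  if (!length(i)) return(NULL)
  ed[i[1L], ]
}

edge_len_now <- function(st, u, w) {
  sqrt(sum((st$V[u, ] - st$V[w, ])^2))
}

# ---------------------------------------------------------------------------
# Snapshot

state_to_frame <- function(st, ed, time) {
  rim_cells <- unique(stats::na.omit(c(ed$c1[is.na(ed$c2)])))
  cells <- lapply(names(st$cells), function(nm) {
    cyc <- st$cells[[nm]]
    list(id = as.integer(nm),
         boundary = st$V[cyc, , drop = FALSE],
         is_boundary_cell = as.integer(nm) %in% rim_cells)
  })
  names(cells) <- names(st$cells)
  inter <- ed[!is.na(ed$c2), , drop = FALSE]
  edges <- lapply(seq_len(nrow(inter)), function(i) {
    list(cells = c(inter$c1[i], inter$c2[i]),
         polyline = rbind(st$V[inter$u[i], ], st$V[inter$w[i], ]))
  })
  epi_frame(cells, edges, time = time)
}

# ---------------------------------------------------------------------------
# Main driver

#' Run the vertex-model simulation
#'
#' @param cfg a [sim_config()].
#' @return list with `tissue` (a [tissue_sequence()]) and `truth`
#'   (data.frame of ground-truth events: type, members, onset_frame,
#'   transition_frame, end_frame, pair_lose, pair_gain).
#' @export
simulate_tissue <- function(cfg) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  st <- hex_lattice(cfg$rows, cfg$cols, cfg$edge_len, cfg$jitter_sd)
  A0 <- st$A0
  ct <- corner_table(st)
  ed <- state_edges(st)
  eta <- 0.5

  # per-event mutable status
  evs <- lapply(cfg$scripted_events, function(e) {
    e$status <- "waiting"
    e$members <- NA_character_
    e$transition_frame <- NA_integer_
    e$end_frame <- NA_integer_
    e$onset_len <- NA_real_
    e$pair_gain <- c(NA_integer_, NA_integer_)
    if (e$type %in% c("rosette", "hub")) {
      e$collapsed <- rep(FALSE, length(e$pairs))
      e$core_vertex <- NA_integer_
      e$hub_stage <- 0L
    }
    e
  })
  frames <- vector("list", cfg$n_frames)
  truth_rows <- list()
  rebuild <- function() {
    ct <<- corner_table(st)
    ed <<- state_edges(st)
  }

  quartet_members <- function(ring, pair) {
    # ring of cells around a 4-fold vertex; losing pair given
    sort(ring)
  }

  for (f in seq_len(cfg$n_frames)) {
    t_now <- (f - 1L) * cfg$frame_interval_s

    # -- 1. scheduled topological resolutions from previous frame
    for (i in seq_along(evs)) {
      e <- evs[[i]]
      if (e$type == "t1" && identical(e$status, "held") &&
          f > e$transition_frame) {
        ring <- vertex_cell_ring(st, e$core_vertex)
        gain <- setdiff(ring, e$pair)
        if (length(gain) != 2L) stop("T1 resolution: unexpected vertex ring")
        sp <- split_vertex(st, e$core_vertex, gain[1L], gain[2L],
                           delta = cfg$t1_swap_threshold * 1.2)
        st <- sp$st
        e$pair_gain <- gain
        e$status <- "growing"
        e$grow_until <- f + cfg$grow_frames
        rebuild()
      } else if (e$type %in% c("rosette", "hub") && identical(e$status, "held") &&
                 f > e$transition_frame + e$hold_frames - 1L) {
        ring <- vertex_cell_ring(st, e$core_vertex)
        if (e$type == "rosette") {
          # resolve: connect the two non-ring-adjacent cells farthest apart
          best <- NULL; bestd <- -1
          n <- length(ring)
          for (a in seq_len(n)) for (b in seq_len(n)) {
            if (b <= a) next
            if ((b - a) %in% c(1L, n - 1L)) next  # ring-adjacent
            ca <- st$cells[[as.character(ring[a])]]
            cb <- st$cells[[as.character(ring[b])]]
            d <- sum((polygon_centroid(st$V[ca, , drop = FALSE]) -
                      polygon_centroid(st$V[cb, , drop = FALSE]))^2)
            if (d > bestd) { bestd <- d; best <- c(ring[a], ring[b]) }
          }
          sp <- split_vertex(st, e$core_vertex, best[1L], best[2L],
                             delta = cfg$t1_swap_threshold * 1.2)
          st <- sp$st
          e$pair_gain <- best
          e$status <- "growing"
          e$grow_until <- f + cfg$grow_frames
          rebuild()
        } else {
          # hub stage 1: release one ring member
          leave <- ring[1L]
          n <- length(ring)
          nb <- c(ring[n], ring[2L])   # ring neighbours of the leaver
          sp <- split_vertex(st, e$core_vertex, nb[1L], nb[2L],
                             delta = cfg$t1_swap_threshold * 1.2)
          st <- sp$st
          # the core vertex is the daughter still shared by >= 4 cells
          cand <- sp$new_edge
          n_inc <- vapply(cand, function(vv) {
            sum(vapply(st$cells, function(cyc) vv %in% cyc, logical(1)))
          }, numeric(1))
          e$core_vertex <- cand[which.max(n_inc)]
          e$left_member <- leave
          e$status <- "hub_released"
          e$hub_release_frame <- f
          rebuild()
        }
      } else if (e$type == "hub" && identical(e$status, "hub_released") &&
                 f >= e$hub_release_frame + 2L) {
        # hub stage 2: recruit a new cell by collapsing a short edge at the core
        m <- e$core_vertex
        ring <- vertex_cell_ring(st, m)
        inc <- ed[(ed$u == m | ed$w == m) & !is.na(ed$c2), , drop = FALSE]
        done <- FALSE
        for (r in seq_len(nrow(inc))) {
          other <- if (inc$u[r] == m) inc$w[r] else inc$u[r]
          joiners <- setdiff(vertex_cell_ring(st, other), ring)
          joiners <- setdiff(joiners, e$left_member)
          if (length(joiners)) {
            st <- collapse_edge_vertices(st, m, other)
            e$core_vertex <- nrow(st$V)
            e$joined_member <- joiners[1L]
            e$status <- "hub_done"
            e$end_frame <- f
            e$members <- group_key(unique(c(key_to_members(e$members),
                                            joiners[1L])))
            rebuild()
            done <- TRUE
            break
          }
        }
        if (!done) { e$status <- "hub_done"; e$end_frame <- f }
      } else if (identical(e$status, "growing") && f >= e$grow_until) {
        e$status <- "done"
        e$end_frame <- f
      }
      evs[[i]] <- e
    }

    # -- 2. activate waiting events
    for (i in seq_along(evs)) {
      e <- evs[[i]]
      if (identical(e$status, "waiting") && f >= e$onset_frame) {
        if (e$type %in% c("t1", "t1_reversal", "pulse")) {
          eg <- current_edge_of_pair(ed, e$pair[1L], e$pair[2L])
          if (is.null(eg)) stop(sprintf("scripted junction %d-%d not found",
                                        e$pair[1L], e$pair[2L]))
          e$onset_len <- edge_len_now(st, eg$u, eg$w)
          e$status <- "contracting"
          if (e$type != "t1") {
            # record the junction quartet as this event's candidate group
            nb_of <- function(cc) {
              stats::na.omit(c(ed$c2[ed$c1 == cc], ed$c1[ed$c2 == cc]))
            }
            common <- intersect(nb_of(e$pair[1L]), nb_of(e$pair[2L]))
            e$members <- group_key(c(e$pair, common[seq_len(min(2L, length(common)))]))
          }
        } else if (e$type == "dilation") {
          e$status <- "active"
          nb <- sort(stats::na.omit(c(ed$c2[ed$c1 == e$cell],
                                      ed$c1[ed$c2 == e$cell])))
          e$members <- group_key(c(e$cell, nb[seq_len(min(3L, length(nb)))]))
        } else {
          e$status <- "contracting"
        }
        evs[[i]] <- e
      }
    }

    # -- 3. assemble tension map and preferred areas for this frame
    lambda <- rep(cfg$lambda_base, nrow(ed))
    A0_now <- A0[names(st$cells)]
    for (i in seq_along(evs)) {
      e <- evs[[i]]
      if (e$type %in% c("t1", "t1_reversal", "pulse") &&
          identical(e$status, "contracting")) {
        eg <- current_edge_of_pair(ed, e$pair[1L], e$pair[2L])
        if (!is.null(eg)) {
          lambda[which(ed$u == eg$u & ed$w == eg$w)] <- cfg$lambda_high
        }
      } else if (e$type %in% c("rosette", "hub") &&
                 e$status %in% c("contracting")) {
        for (j in seq_along(e$pairs)) {
          if (e$collapsed[j]) next
          if (f < e$onset_frame + (j - 1L) * e$stagger_frames) next
          eg <- current_edge_of_pair(ed, e$pairs[[j]][1L], e$pairs[[j]][2L])
          if (!is.null(eg)) {
            lam_hi <- if (is.null(e$lambda)) 2.5 * cfg$lambda_high else e$lambda
            lambda[which(ed$u == eg$u & ed$w == eg$w)] <- lam_hi
          }
        }
      } else if (e$status %in% c("growing", "done") &&
                 !any(is.na(e$pair_gain))) {
        eg <- current_edge_of_pair(ed, e$pair_gain[1L], e$pair_gain[2L])
        if (!is.null(eg)) {
          lam <- if (identical(e$status, "growing")) cfg$lambda_grow else cfg$lambda_stab
          lambda[which(ed$u == eg$u & ed$w == eg$w)] <- lam
        }
      } else if (e$type == "dilation" && identical(e$status, "active")) {
        if (f < e$onset_frame + e$duration) {
          A0_now[as.character(e$cell)] <- A0[as.character(e$cell)] * e$factor
        } else {
          evs[[i]]$status <- "done"
          evs[[i]]$end_frame <- f
        }
      }
    }

    # -- 4. relax
    res <- relax_steps(st, ct, ed, lambda, cfg, A0_now, cfg$n_relax, eta)
    st <- res$st; eta <- max(res$eta, 1e-4)

    # -- 5. release / collapse checks
    for (i in seq_along(evs)) {
      e <- evs[[i]]
      if (e$type %in% c("t1_reversal", "pulse") &&
          identical(e$status, "contracting")) {
        eg <- current_edge_of_pair(ed, e$pair[1L], e$pair[2L])
        len <- edge_len_now(st, eg$u, eg$w)
        if (len <= e$release_frac * e$onset_len) {
          e$status <- "recovering"
          e$min_frame <- f
        }
      } else if (identical(e$status, "recovering")) {
        eg <- current_edge_of_pair(ed, e$pair[1L], e$pair[2L])
        len <- edge_len_now(st, eg$u, eg$w)
        if (len >= 0.9 * e$onset_len) {
          e$status <- "done"
          e$end_frame <- f
        }
      } else if (e$type == "t1" && identical(e$status, "contracting")) {
        eg <- current_edge_of_pair(ed, e$pair[1L], e$pair[2L])
        len <- edge_len_now(st, eg$u, eg$w)
        if (len < cfg$t1_swap_threshold) {
          st <- collapse_edge_vertices(st, eg$u, eg$w)
          e$core_vertex <- nrow(st$V)
          ring <- vertex_cell_ring(st, e$core_vertex)
          e$members <- group_key(ring)
          e$transition_frame <- f
          e$status <- "held"
          rebuild()
        }
      } else if (e$type %in% c("rosette", "hub") &&
                 identical(e$status, "contracting")) {
        changed <- FALSE
        for (j in seq_along(e$pairs)) {
          if (e$collapsed[j]) next
          eg <- current_edge_of_pair(ed, e$pairs[[j]][1L], e$pairs[[j]][2L])
          if (is.null(eg)) next
          len <- edge_len_now(st, eg$u, eg$w)
          if (len < cfg$t1_swap_threshold) {
            st <- collapse_edge_vertices(st, eg$u, eg$w)
            e$collapsed[j] <- TRUE
            e$core_vertex <- nrow(st$V)
            changed <- TRUE
            rebuild()
            ed <- state_edges(st)
          }
        }
        if (changed && all(e$collapsed)) {
          ring <- vertex_cell_ring(st, e$core_vertex)
          e$members <- group_key(ring)
          e$transition_frame <- f
          e$status <- "held"
          if (is.null(e$hold_frames)) e$hold_frames <- 1L
        }
      }
      evs[[i]] <- e
    }
    rebuild()

    # -- 6. snapshot
    frames[[f]] <- state_to_frame(st, ed, t_now)
  }

  truth <- do.call(rbind, lapply(evs, function(e) {
    members <- if (!is.na(e$members)) e$members else {
      if (!is.null(e$pair)) group_key(e$pair)
      else if (!is.null(e$pairs)) group_key(unique(unlist(e$pairs)))
      else group_key(e$cell)
    }
    data.frame(
      type = e$type,
      members = members,
      onset_frame = e$onset_frame,
      transition_frame = if (is.na(e$transition_frame)) NA_integer_ else e$transition_frame,
      end_frame = if (is.na(e$end_frame)) cfg$n_frames else e$end_frame,
      pair_lose = if (!is.null(e$pair)) group_key(e$pair) else NA_character_,
      pair_gain = if (!any(is.na(e$pair_gain))) group_key(e$pair_gain) else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(truth)) {
    truth <- data.frame(type = character(0), members = character(0),
                        onset_frame = integer(0), transition_frame = integer(0),
                        end_frame = integer(0), pair_lose = character(0),
                        pair_gain = character(0))
  }
  list(tissue = tissue_sequence(frames, pixel_size = cfg$pixel_size),
       truth = truth)
}
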