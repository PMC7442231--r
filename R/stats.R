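# Downstream quantification of mapped motifs: frequency with boundary
# correction, junction kinetics, junction orientation against a fitted
# midline, circular statistics, rosette sequentiality and rosette-hub
# detection.

#' Motif frequency with boundary correction
#'
#' Events whose cells partly overlap the field-of-view border are counted
#' fractionally: each event contributes the fraction of its cells that are
#' non-boundary cells, the sum is divided by the number of non-boundary
#' cells and by the event size k, converted to per-minute via `dt_min` and
#' scaled to a 100-cell tissue.
#'
#' @param event_members list of integer vectors (one member set per event
#'   appearing in the frame).
#' @param frame an `epi_frame` with boundary flags.
#' @param dt_min inter-frame interval in minutes.
#' @param k event size (4 for T1s; 5 or 6 for rosettes, generalising the
#'   1/k factor).
#' @return events per 100 cells per minute.
#' @export
motif_frequency <- function(event_members, frame, dt_min, k) {
  is_bnd <- vapply(frame$cells, function(cl) isTRUE(cl$is_boundary_cell),
                   logical(1))
  interior <- frame_cell_ids(frame)[!is_bnd]
  if (!length(interior)) stop("no non-boundary cells: frequency undefined")
  frac <- vapply(event_members, function(mem) {
    length(intersect(mem, interior)) / length(interior)
  }, numeric(1))
  100 * sum(frac) / (k * dt_min)
}

# -- junction kinetics -------------------------------------------------------

# Truncate a junction-length trace at the intercalation gap: a contracting
# junction is kept up to the first zero-length time point; a growing junction
# starts at the onset of persistent growth (first of >= 2 consecutive
# positive lengths).
truncate_junction_trace <- function(lengths, times, role = c("contracting", "growing")) {
  role <- match.arg(role)
  if (role == "contracting") {
    z <- which(lengths <= 0)
    if (length(z)) {
      keep <- seq_len(z[1L])
      lengths <- lengths[keep]; times <- times[keep]
    }
  } else {
    pos <- lengths > 0
    run2 <- which(pos & c(pos[-1L], FALSE))
    if (length(run2)) {
      keep <- run2[1L]:length(lengths)
      lengths <- lengths[keep]; times <- times[keep]
    }
  }
  list(lengths = lengths, times = times)
}

# Centred moving average of width w; the window shrinks symmetrically at the
# ends (width 1 at the first/last point), so linear signals pass unchanged.
.ma_smooth <- function(x, w = 3L) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(x[(i - r):(i + r)])
  }, numeric(1))
}

#' Junction length kinetics
#'
#' Processes one junction-length trace: truncation at the intercalation gap,
#' centred moving-average smoothing (default width 3), linear resampling to
#' a standard interval (default 30 s) and finite differencing.
#'
#' @param lengths junction lengths (um), one per frame.
#' @param times_min frame times in minutes.
#' @param role `"contracting"` or `"growing"` (controls truncation).
#' @param target_dt_s resampling interval in seconds.
#' @param smooth_w moving-average width in frames.
#' @return list with `times` (min), `lengths` (um, resampled), `rate_times`
#'   (interval midpoints, min) and `rates` (um/min), or NULL with a warning
#'   when the trace is shorter than the smoothing window.
#' @export
junction_kinetics <- function(lengths, times_min,
                              role = c("contracting", "growing"),
                              target_dt_s = 30, smooth_w = 3L) {
  role <- match.arg(role)
  tr <- truncate_junction_trace(lengths, times_min, role)
  if (length(tr$lengths) < smooth_w) {
    warning("trace shorter than the smoothing window; skipped")
    return(NULL)
  }
  sm <- .ma_smooth(tr$lengths, smooth_w)
  dt <- target_dt_s / 60
  tt <- seq(tr$times[1L], tr$times[length(tr$times)], by = dt)
  ll <- stats::approx(tr$times, sm, xout = tt)$y
  rates <- diff(ll) / dt
  list(times = tt, lengths = ll,
       rate_times = (tt[-1L] + tt[-length(tt)]) / 2, rates = rates)
}

#' Event-averaged junction rate curve
#'
#' Aligns processed traces on their final time point, keeps the last
#' `window_min` minutes and discards traces that persist for less, then
#' averages the rates across events.
#'
#' @param kinetics list of [junction_kinetics()] results.
#' @param window_min length of the terminal window in minutes.
#' @return list with `t_rel_min` (time before trace end, negative to 0) and
#'   `mean_rate` (um/min), plus `n_used`.
#' @export
average_kinetics <- function(kinetics, window_min = 10) {
  kinetics <- Filter(Negate(is.null), kinetics)
  dt <- if (length(kinetics)) diff(kinetics[[1L]]$times[1:2]) else NA_real_
  n_pts <- round(window_min / dt)
  used <- Filter(function(kk) length(kk$rates) >= n_pts, kinetics)
  if (!length(used)) {
    return(list(t_rel_min = numeric(0), mean_rate = numeric(0), n_used = 0L))
  }
  mat <- vapply(used, function(kk) {
    utils::tail(kk$rates, n_pts)
  }, numeric(n_pts))
  list(t_rel_min = seq(-(n_pts - 1L), 0) * dt, mean_rate = rowMeans(mat),
       n_used = length(used))
}

# -- junction orientation ----------------------------------------------------

#' Fit a tissue midline from anchor points
#'
#' Anchor points (a few clicked positions on selected frames) are fitted per
#' anchor frame with a polynomial of degree min(n_points - 1, 4); the
#' coefficients are interpolated to all frames with a monotone piecewise
#' cubic (Fritsch-Carlson) rule.
#'
#' @param anchors data.frame with columns `frame`, `x`, `y`.
#' @param frames_total total number of frames to cover.
#' @return a `midline`: list with `coef` (frames_total x 5 matrix, columns
#'   a0..a4 of y(x) = sum a_i x^i).
#' @export
fit_midline <- function(anchors, frames_total) {
  afr <- sort(unique(anchors$frame))
  co <- matrix(0, length(afr), 5L)
  for (r in seq_along(afr)) {
    sel <- anchors[anchors$frame == afr[r], ]
    deg <- min(nrow(sel) - 1L, 4L)
    fit <- stats::lm(y ~ stats::poly(x, degree = deg, raw = TRUE), data = sel)
    co[r, seq_len(deg + 1L)] <- stats::coef(fit)
  }
  co[is.na(co)] <- 0
  out <- matrix(0, frames_total, 5L)
  for (cc in 1:5) {
    out[, cc] <- if (length(afr) == 1L) {
      rep(co[1L, cc], frames_total)
    } else {
      f <- stats::splinefun(afr, co[, cc], method = "monoH.FC")
      f(pmin(pmax(seq_len(frames_total), min(afr)), max(afr)))
    }
  }
  colnames(out) <- paste0("a", 0:4)
  structure(list(coef = out), class = "midline")
}

midline_y <- function(midline, frame, x) {
  a <- unname(midline$coef[frame, ])
  a[1L] + a[2L] * x + a[3L] * x^2 + a[4L] * x^3 + a[5L] * x^4
}

midline_slope <- function(midline, frame, x) {
  a <- unname(midline$coef[frame, ])
  a[2L] + 2 * a[3L] * x + 3 * a[4L] * x^2 + 4 * a[5L] * x^3
}

# x of the closest midline point to p, by dense sampling over [x_lo, x_hi]
# plus one quadratic refinement around the best sample.
closest_midline_x <- function(midline, frame, p, x_lo, x_hi, n = 1000L) {
  xs <- seq(x_lo, x_hi, length.out = n)
  ys <- midline_y(midline, frame, xs)
  d2 <- (xs - p[1L])^2 + (ys - p[2L])^2
  i <- which.min(d2)
  if (i == 1L || i == n) return(xs[i])
  x3 <- xs[(i - 1L):(i + 1L)]; y3 <- d2[(i - 1L):(i + 1L)]
  denom <- (x3[1L] - x3[2L]) * (x3[1L] - x3[3L]) * (x3[2L] - x3[3L])
  A <- (x3[3L] * (y3[2L] - y3[1L]) + x3[2L] * (y3[1L] - y3[3L]) +
        x3[1L] * (y3[3L] - y3[2L])) / denom
  B <- (x3[3L]^2 * (y3[1L] - y3[2L]) + x3[2L]^2 * (y3[3L] - y3[1L]) +
        x3[1L]^2 * (y3[2L] - y3[3L])) / denom
  if (abs(A) < 1e-12) return(xs[i])
  max(x_lo, min(x_hi, -B / (2 * A)))
}

#' Angle between a junction and the tissue midline
#'
#' Acute angle (degrees in [0, 90]) between the edge through the two given
#' points and the midline tangent at the midline point closest to the edge
#' midpoint.
#'
#' @param p0,p1 edge endpoints (length-2 numeric, um).
#' @param midline a [fit_midline()] object.
#' @param frame frame index.
#' @param x_range x-range over which the midline is searched (default: a
#'   window around the edge midpoint).
#' @return angle in degrees.
#' @export
junction_angle <- function(p0, p1, midline, frame, x_range = NULL) {
  mid <- (p0 + p1) / 2
  if (is.null(x_range)) x_range <- c(mid[1L] - 50, mid[1L] + 50)
  xt <- closest_midline_x(midline, frame, mid, x_range[1L], x_range[2L])
  a_ml <- atan(midline_slope(midline, frame, xt))
  a_e <- atan2(p1[2L] - p0[2L], p1[1L] - p0[1L])
  d <- abs(a_ml - a_e) * 180 / pi
  d <- d %% 180
  if (d > 90) d <- 180 - d
  d
}

#' Duplicate axial angles for rose-plot display
#'
#' Junction orientations have perfect two-fold symmetry; for display each
#' angle is duplicated at alpha + 180 degrees.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return vector of length 2n.
#' @export
axial_duplicate <- function(angles_deg) c(angles_deg, angles_deg + 180)

#' Rayleigh test for circular uniformity (with axial doubling)
#'
#' Axial data (two-fold symmetric angles) are doubled before testing.
#' Returns the Rayleigh statistic z = n * Rbar^2 and the standard series
#' approximation of the p-value.
#'
#' @param angles_deg angles in degrees.
#' @param axial double the angles before testing (default TRUE).
#' @return list with `z`, `p`, `n`, `Rbar`.
#' @export
rayleigh_axial_test <- function(angles_deg, axial = TRUE) {
  n <- length(angles_deg)
  if (n < 4L) stop("Rayleigh test needs at least 4 angles")
  th <- angles_deg * pi / 180
  if (axial) th <- 2 * th
  C <- sum(cos(th)); S <- sum(sin(th))
  Rbar <- sqrt(C^2 + S^2) / n
  z <- n * Rbar^2
  Rn <- Rbar * n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(z = z, p = min(1, p), n = n, Rbar = Rbar)
}

# -- rosette structure -------------------------------------------------------

#' Sequentiality of rosette junction contraction / growth
#'
#' For a rosette event with several contracting junctions, returns the
#' interval between the first and the last junction disappearance, and the
#' analogous interval between the onsets of persistent growth on the growing
#' side; events are classed `"synchronous"` when the interval does not
#' exceed `gap_threshold_min`.
#'
#' @param contract_traces list of lists with `lengths` and `times_min` for
#'   each contracting junction.
#' @param grow_traces same for growing junctions (optional).
#' @param gap_threshold_min gap (minutes) separating synchronous from
#'   sequential formation.
#' @return list with `contract_interval_min`, `grow_interval_min` (NA when
#'   not computable) and `mode`.
#' @export
rosette_sequentiality <- function(contract_traces, grow_traces = NULL,
                                  gap_threshold_min = 0.75) {
  if (length(contract_traces) < 2L) {
    stop("rosette sequentiality needs at least two contracting junctions")
  }
  t_dis <- vapply(contract_traces, function(tr) {
    z <- which(tr$lengths <= 0)
    if (!length(z)) return(NA_real_)
    tr$times_min[z[1L]]
  }, numeric(1))
  if (anyNA(t_dis)) stop("a contracting junction never reaches zero length")
  ci <- max(t_dis) - min(t_dis)
  gi <- NA_real_
  if (!is.null(grow_traces) && length(grow_traces) >= 2L) {
    t_on <- vapply(grow_traces, function(tr) {
      pos <- tr$lengths > 0
      run2 <- which(pos & c(pos[-1L], FALSE))
      if (!length(run2)) return(NA_real_)
      tr$times_min[run2[1L]]
    }, numeric(1))
    if (!anyNA(t_on)) gi <- max(t_on) - min(t_on)
  }
  list(contract_interval_min = ci, grow_interval_min = gi,
       mode = if (ci <= gap_threshold_min) "synchronous" else "sequential")
}

# Per-frame high-order vertices: points shared by >= min_core cell polygons.
.frame_core_vertices <- function(frame, min_core = 4L, tol = 1e-4) {
  pts <- list(); owners <- list()
  for (cl in frame$cells) {
    b <- cl$boundary
    for (r in seq_len(nrow(b))) {
      key <- sprintf("%.4f_%.4f", round(b[r, 1L] / tol) * tol,
                     round(b[r, 2L] / tol) * tol)
      owners[[key]] <- unique(c(owners[[key]], cl$id))
      pts[[key]] <- b[r, ]
    }
  }
  keep <- names(owners)[vapply(owners, length, integer(1)) >= min_core]
  list(points = pts[keep], owners = owners[keep])
}

#' Detect rosette hubs
#'
#' A rosette hub is iterative intercalation at a persistent core vertex: at
#' least one cell separates from the rosette and at least one new cell joins
#' afterwards, while at least `min_core` cells keep surrounding the vertex
#' throughout.
#'
#' @param seq a `tissue_sequence`.
#' @param min_core minimum number of cells around the core vertex.
#' @param match_radius maximum displacement (um) of the core vertex between
#'   consecutive frames.  A junction collapse at the core moves the vertex by
#'   up to half the collapsed junction's length, so the default covers a
#'   typical 3-4 um cell edge.
#' @return data.frame of hub events: `members` (key over all participants),
#'   `first_frame`, `last_frame`, `left`, `joined`.
#' @export
detect_rosette_hub <- function(seq, min_core = 4L, match_radius = 2) {
  nf <- n_frames(seq)
  per_frame <- lapply(seq$frames, .frame_core_vertices, min_core = min_core)
  # link core vertices across frames by proximity
  tracks <- list()   # each: list(pos, frames, owner_sets)
  for (f in seq_len(nf)) {
    cv <- per_frame[[f]]
    for (i in seq_along(cv$points)) {
      p <- cv$points[[i]]; ow <- cv$owners[[i]]
      linked <- FALSE
      for (t in seq_along(tracks)) {
        tr <- tracks[[t]]
        if (tr$frames[length(tr$frames)] == f - 1L &&
            sqrt(sum((tr$pos - p)^2)) <= match_radius) {
          tracks[[t]]$pos <- p
          tracks[[t]]$frames <- c(tr$frames, f)
          tracks[[t]]$owner_sets <- c(tr$owner_sets, list(ow))
          linked <- TRUE
          break
        }
      }
      if (!linked) {
        tracks[[length(tracks) + 1L]] <- list(pos = p, frames = f,
                                              owner_sets = list(ow))
      }
    }
  }
  out <- list()
  for (tr in tracks) {
    if (length(tr$frames) < 2L) next
    sets <- tr$owner_sets
    left <- integer(0); joined <- integer(0)
    seen_leave <- FALSE
    for (s in 2:length(sets)) {
      gone <- setdiff(sets[[s - 1L]], sets[[s]])
      new <- setdiff(sets[[s]], sets[[s - 1L]])
      if (length(gone)) { left <- union(left, gone); seen_leave <- TRUE }
      if (length(new) && seen_leave) joined <- union(joined, new)
    }
    if (length(left) && length(joined)) {
      out[[length(out) + 1L]] <- data.frame(
        members = group_key(unique(unlist(sets))),
        first_frame = tr$frames[1L],
        last_frame = tr$frames[length(tr$frames)],
        left = group_key(left),
        joined = group_key(joined),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(members = character(0), first_frame = integer(0),
                      last_frame = integer(0), left = character(0),
                      joined = character(0)))
  }
  do.call(rbind, out)
}
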