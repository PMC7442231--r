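# Planar geometry primitives shared by the tissue representation and the
# feature extractors.  All coordinates are in micrometres unless a function
# says otherwise; polygons are N x 2 matrices, open (last vertex != first),
# and traversed counter-clockwise in a y-down image coordinate frame.

#' Length of a polyline
#'
#' Sum of the Euclidean lengths of the straight segments joining consecutive
#' points of a polyline, the same convention used for junction lengths.
#'
#' @param pts numeric matrix with columns x, y (>= 2 rows).
#' @return total length (same units as the coordinates).
#' @export
polyline_length <- function(pts) {
  pts <- as_xy_matrix(pts)
  if (nrow(pts) < 2L) stop("polyline needs at least 2 points")
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

as_xy_matrix <- function(pts) {
  m <- if (is.matrix(pts)) pts else do.call(rbind, lapply(pts, as.numeric))
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("expected an N x 2 coordinate matrix")
  m
}

#' Shoelace area of a polygon
#'
#' Signed area is positive for counter-clockwise orientation in a standard
#' (y-up) frame; callers that only need the magnitude should use `abs()`.
#'
#' @param poly N x 2 matrix of vertices, open ring.
#' @param signed return the signed area (default FALSE).
#' @return area.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_xy_matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  a <- 0.5 * sum(poly[, 1L] * poly[j, 2L] - poly[j, 1L] * poly[, 2L])
  if (signed) a else abs(a)
}

polygon_centroid <- function(poly) {
  poly <- as_xy_matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(colMeans(poly))
  j <- c(2:n, 1L)
  cr <- poly[, 1L] * poly[j, 2L] - poly[j, 1L] * poly[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  cx <- sum((poly[, 1L] + poly[j, 1L]) * cr) / (6 * a)
  cy <- sum((poly[, 2L] + poly[j, 2L]) * cr) / (6 * a)
  c(cx, cy)
}

# Perpendicular distance of points to the (infinite) line through a, b;
# degenerates to point distance when a == b.
.dist_point_line <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-24) return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  abs((pts[, 1L] - a[1L]) * ab[2L] - (pts[, 2L] - a[2L]) * ab[1L]) / sqrt(len2)
}

#' Douglas-Peucker polyline simplification
#'
#' Recursively removes interior points whose perpendicular distance to the
#' chord of the current span is below `tol`.  Endpoints are always kept, so
#' the simplified polyline never gains points and never moves its ends.
#'
#' @param pts N x 2 polyline.
#' @param tol distance tolerance (same units as coordinates).
#' @return simplified polyline matrix.
#' @export
dp_simplify <- function(pts, tol) {
  pts <- as_xy_matrix(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    span <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- span[1L]; j <- span[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .dist_point_line(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    w <- which.max(d)
    if (d[w] > tol) {
      m <- mid[w]
      keep[m] <- TRUE
      stack <- c(stack, list(c(i, m)), list(c(m, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Minimum distance between a set of points and a set of segments.
# pts: N x 2; seg_a, seg_b: M x 2 endpoints.  Returns N x M matrix.
.dist_points_segments <- function(pts, seg_a, seg_b) {
  n <- nrow(pts); m <- nrow(seg_a)
  ab <- seg_b - seg_a
  len2 <- rowSums(ab^2)
  len2[len2 < 1e-24] <- 1e-24
  # t = clamp(dot(p - a, ab) / |ab|^2)
  px <- matrix(pts[, 1L], n, m)
  py <- matrix(pts[, 2L], n, m)
  ax <- matrix(seg_a[, 1L], n, m, byrow = TRUE)
  ay <- matrix(seg_a[, 2L], n, m, byrow = TRUE)
  abx <- matrix(ab[, 1L], n, m, byrow = TRUE)
  aby <- matrix(ab[, 2L], n, m, byrow = TRUE)
  tt <- ((px - ax) * abx + (py - ay) * aby) / matrix(len2, n, m, byrow = TRUE)
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  dx <- px - (ax + tt * abx)
  dy <- py - (ay + tt * aby)
  sqrt(dx * dx + dy * dy)
}

.segments_of <- function(pts, closed = FALSE) {
  pts <- as_xy_matrix(pts)
  n <- nrow(pts)
  if (closed) {
    list(a = pts, b = pts[c(2:n, 1L), , drop = FALSE])
  } else {
    list(a = pts[-n, , drop = FALSE], b = pts[-1L, , drop = FALSE])
  }
}

.segments_intersect <- function(a1, b1, a2, b2) {
  # proper/improper intersection test between two segment sets (any pair)
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  n1 <- nrow(a1); n2 <- nrow(a2)
  for (i in seq_len(n1)) {
    d1 <- cross(a1[i, 1L], a1[i, 2L], b1[i, 1L], b1[i, 2L], a2[, 1L], a2[, 2L])
    d2 <- cross(a1[i, 1L], a1[i, 2L], b1[i, 1L], b1[i, 2L], b2[, 1L], b2[, 2L])
    d3 <- cross(a2[, 1L], a2[, 2L], b2[, 1L], b2[, 2L], a1[i, 1L], a1[i, 2L])
    d4 <- cross(a2[, 1L], a2[, 2L], b2[, 1L], b2[, 2L], b1[i, 1L], b1[i, 2L])
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(TRUE)
  }
  FALSE
}

#' Minimum distance between two polylines
#'
#' True segment-to-segment minimum distance (not vertex-to-vertex): each
#' polyline's vertices are tested against the other's segments, and crossing
#' segments yield distance zero.
#'
#' @param p,q polylines (N x 2 matrices).
#' @param closed_p,closed_q treat the polyline as a closed ring.
#' @return minimum Euclidean distance; 0 if the polylines touch or cross.
#' @export
polyline_distance <- function(p, q, closed_p = FALSE, closed_q = FALSE) {
  p <- as_xy_matrix(p); q <- as_xy_matrix(q)
  sp <- .segments_of(p, closed_p); sq <- .segments_of(q, closed_q)
  d <- min(.dist_points_segments(p, sq$a, sq$b),
           .dist_points_segments(q, sp$a, sp$b))
  if (d > 0 && .segments_intersect(sp$a, sp$b, sq$a, sq$b)) d <- 0
  d
}

#' Point-in-polygon test (ray casting)
#'
#' @param pt length-2 numeric.
#' @param poly N x 2 polygon, open ring.
#' @return TRUE if strictly inside (boundary points count as inside).
#' @export
point_in_polygon <- function(pt, poly) {
  poly <- as_xy_matrix(poly)
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x <- pt[1L]; y <- pt[2L]
  xi <- poly[, 1L]; yi <- poly[, 2L]
  xj <- poly[j, 1L]; yj <- poly[j, 2L]
  crosses <- ((yi > y) != (yj > y)) &
    (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
  sum(crosses) %% 2L == 1L
}
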