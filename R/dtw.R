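# Constrained dynamic time warping: full-sequence scoring, open-begin /
# open-end subsequence matching, phase-label transfer and non-maximum
# suppression of overlapping matches.
#
# The step pattern is {(1,1), (1,0), (0,1)} with unit weights; the score is
# the sum of Euclidean distances between matched feature vectors, and the
# normalised score divides by the warping-path length (the average distance
# per matched pair).  Unbounded stretching is prevented by capping the number
# of repetitions of any single time point.

#' DTW configuration
#'
#' @param max_repeat maximum number of times a single time point of either
#'   sequence may be matched (>= 1; 1 forbids any stretching).
#' @param slope_bound optional maximum local slope of the warping path; when
#'   given it is enforced through the equivalent repetition cap
#'   `max_repeat = max(1, round(slope_bound))`.
#' @return a `dtw_config` list.
#' @export
dtw_config <- function(max_repeat = 3L, slope_bound = NULL) {
  if (!is.null(slope_bound)) max_repeat <- max(1L, as.integer(round(slope_bound)))
  stopifnot(max_repeat >= 1L)
  structure(list(max_repeat = as.integer(max_repeat)), class = "dtw_config")
}

.cost_matrix <- function(TV, CV) {
  # Euclidean norm between every template / candidate feature-vector pair
  TV <- as.matrix(TV); CV <- as.matrix(CV)
  if (ncol(TV) != ncol(CV)) stop("feature dimension mismatch between series")
  d2 <- outer(rowSums(TV^2), rep(1, nrow(CV))) +
    outer(rep(1, nrow(TV)), rowSums(CV^2)) - 2 * TV %*% t(CV)
  sqrt(pmax(d2, 0))
}

# Core DP.  States per cell: 1 = arrived diagonally (or path start),
# 2..R = vertical run 1..R-1 (template advancing, candidate point repeated),
# R+1..2R-1 = horizontal run 1..R-1 (candidate advancing, template point
# repeated), where R = max_repeat.  Ties prefer diagonal, then
# template-advance, for reproducible paths.
.dtw_dp <- function(cost, max_repeat, open_begin = FALSE) {
  m <- nrow(cost); n <- ncol(cost)
  R <- max_repeat
  nv <- R - 1L; nh <- R - 1L
  S <- 1L + nv + nh
  INF <- Inf
  D <- array(INF, c(m, n, S))
  P <- array(0L, c(m, n, S))      # predecessor state (0 = path start)
  L <- array(0L, c(m, n, S))      # path length (matched pairs)
  v_states <- if (nv) 1L + seq_len(nv) else integer(0)
  h_states <- if (nh) 1L + nv + seq_len(nh) else integer(0)
  # preference order for argmin ties: diagonal, then vertical runs, then horizontal
  pick <- function(vals) {
    fin <- which(is.finite(vals))
    if (!length(fin)) return(0L)
    fin[which.min(vals[fin])]
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cc <- cost[i, j]
      # diagonal state
      if (i == 1L && (j == 1L || open_begin)) {
        D[i, j, 1L] <- cc; P[i, j, 1L] <- 0L; L[i, j, 1L] <- 1L
      }
      if (i > 1L && j > 1L) {
        prev <- D[i - 1L, j - 1L, ]
        s <- pick(prev)
        if (s > 0L && prev[s] + cc < D[i, j, 1L]) {
          D[i, j, 1L] <- prev[s] + cc
          P[i, j, 1L] <- s
          L[i, j, 1L] <- L[i - 1L, j - 1L, s] + 1L
        }
      }
      # vertical states (advance template, repeat candidate point j)
      if (i > 1L && nv) {
        allowed <- c(1L, h_states)
        prev <- D[i - 1L, j, allowed]
        s <- pick(prev)
        if (s > 0L) {
          D[i, j, v_states[1L]] <- prev[s] + cc
          P[i, j, v_states[1L]] <- allowed[s]
          L[i, j, v_states[1L]] <- L[i - 1L, j, allowed[s]] + 1L
        }
        if (nv > 1L) for (r in 2:nv) {
          pv <- D[i - 1L, j, v_states[r - 1L]]
          if (is.finite(pv)) {
            D[i, j, v_states[r]] <- pv + cc
            P[i, j, v_states[r]] <- v_states[r - 1L]
            L[i, j, v_states[r]] <- L[i - 1L, j, v_states[r - 1L]] + 1L
          }
        }
      }
      # horizontal states (advance candidate, repeat template point i)
      if (j > 1L && nh) {
        allowed <- c(1L, v_states)
        prev <- D[i, j - 1L, allowed]
        s <- pick(prev)
        if (s > 0L) {
          D[i, j, h_states[1L]] <- prev[s] + cc
          P[i, j, h_states[1L]] <- allowed[s]
          L[i, j, h_states[1L]] <- L[i, j - 1L, allowed[s]] + 1L
        }
        if (nh > 1L) for (r in 2:nh) {
          pv <- D[i, j - 1L, h_states[r - 1L]]
          if (is.finite(pv)) {
            D[i, j, h_states[r]] <- pv + cc
            P[i, j, h_states[r]] <- h_states[r - 1L]
            L[i, j, h_states[r]] <- L[i, j - 1L, h_states[r - 1L]] + 1L
          }
        }
      }
    }
  }
  list(D = D, P = P, L = L, m = m, n = n, R = R,
       v_states = v_states, h_states = h_states)
}

# Backtrack from (m, j_end, s_end); returns wp_t, wp_c index vectors.
.dtw_backtrack <- function(dp, j_end, s_end) {
  wp_t <- integer(0); wp_c <- integer(0)
  i <- dp$m; j <- j_end; s <- s_end
  repeat {
    wp_t <- c(i, wp_t); wp_c <- c(j, wp_c)
    ps <- dp$P[i, j, s]
    if (ps == 0L && i == 1L) break
    if (s == 1L) { i <- i - 1L; j <- j - 1L }
    else if (s %in% dp$v_states) i <- i - 1L
    else j <- j - 1L
    s <- ps
  }
  list(wp_t = wp_t, wp_c = wp_c)
}

.best_state <- function(dp, i, j) {
  vals <- dp$D[i, j, ]
  fin <- which(is.finite(vals))
  if (!length(fin)) return(0L)
  fin[which.min(vals[fin])]
}

#' Full-sequence constrained DTW score
#'
#' Aligns the whole of `T` against the whole of `S` and returns the raw
#' summed distance together with the optimal warping path.  Tie-breaking
#' prefers diagonal steps, then template advances.
#'
#' @param T,S numeric matrices (rows = time points, columns = features) or
#'   objects with a `values` matrix (templates, candidate series).
#' @param cfg a [dtw_config()].
#' @return list with `raw_score`, `norm_score` (raw / path length), `wp_t`,
#'   `wp_c`.
#' @export
dtw_score <- function(T, S, cfg = dtw_config()) {
  TV <- if (is.list(T) && !is.null(T$values)) T$values else T
  SV <- if (is.list(S) && !is.null(S$values)) S$values else S
  if (is.vector(TV)) TV <- matrix(TV, ncol = 1L)
  if (is.vector(SV)) SV <- matrix(SV, ncol = 1L)
  cost <- .cost_matrix(TV, SV)
  dp <- .dtw_dp(cost, cfg$max_repeat, open_begin = FALSE)
  s <- .best_state(dp, dp$m, dp$n)
  if (s == 0L) stop("no admissible warping path under the repetition bound")
  path <- .dtw_backtrack(dp, dp$n, s)
  raw <- dp$D[dp$m, dp$n, s]
  list(raw_score = raw, norm_score = raw / length(path$wp_t),
       wp_t = path$wp_t, wp_c = path$wp_c)
}

#' Open-ended subsequence match of a template in a candidate series
#'
#' The full template is warped against the best subsequence `C[i..j]`: entry
#' is free anywhere along the candidate axis (open begin) and the score is
#' read out along the final template row (open end), minimising the
#' normalised score raw / |WP|.
#'
#' @param template a `motif_template` (or plain matrix).
#' @param candidate a `candidate_series` (or plain matrix).
#' @param cfg a [dtw_config()].
#' @param all_minima also return secondary local minima of the end-score
#'   profile separated by at least half a template length.
#' @return a `motif_match` (list with `i`, `j` — candidate row indices —,
#'   `wp_t`, `wp_c`, `raw_score`, `norm_score`, `phases`, `members`,
#'   `frames`); with `all_minima = TRUE`, a list of them.
#' @export
subsequence_match <- function(template, candidate, cfg = dtw_config(),
                              all_minima = FALSE) {
  TV <- if (is.list(template) && !is.null(template$values)) template$values else template
  CV <- if (is.list(candidate) && !is.null(candidate$values)) candidate$values else candidate
  if (is.vector(TV)) TV <- matrix(TV, ncol = 1L)
  if (is.vector(CV)) CV <- matrix(CV, ncol = 1L)
  cost <- .cost_matrix(TV, CV)
  dp <- .dtw_dp(cost, cfg$max_repeat, open_begin = TRUE)
  n <- dp$n; m <- dp$m
  end_norm <- rep(Inf, n)
  end_state <- integer(n)
  for (j in seq_len(n)) {
    s <- .best_state(dp, m, j)
    end_state[j] <- s
    if (s > 0L) end_norm[j] <- dp$D[m, j, s] / dp$L[m, j, s]
  }
  build <- function(j) {
    s <- end_state[j]
    path <- .dtw_backtrack(dp, j, s)
    mt <- structure(list(
      i = path$wp_c[1L], j = j,
      wp_t = path$wp_t, wp_c = path$wp_c,
      raw_score = dp$D[m, j, s],
      norm_score = end_norm[j],
      members = if (is.list(candidate)) candidate$members else NULL,
      frames = if (is.list(candidate) && !is.null(candidate$frames)) {
        candidate$frames[c(path$wp_c[1L], j)]
      } else c(path$wp_c[1L], j),
      phases = NULL, label = "unlabeled"
    ), class = "motif_match")
    if (is.list(template) && !is.null(template$phases)) {
      mt$phases <- transfer_phases(mt, template)
    }
    mt
  }
  j_best <- which.min(end_norm)
  if (!all_minima) return(build(j_best))
  # local minima of the end profile, separated by >= m/2 candidate frames
  ord <- order(end_norm)
  picked <- integer(0)
  for (j in ord) {
    if (!is.finite(end_norm[j])) next
    if (all(abs(j - picked) >= m / 2)) picked <- c(picked, j)
  }
  lapply(sort(picked), build)
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("<motif_match> cells {%s} rows %d..%d, norm score %.4g\n",
              paste(x$members, collapse = ","), x$i, x$j, x$norm_score))
  invisible(x)
}

#' Transfer template phase labels onto matched candidate frames
#'
#' Every matched candidate time point inherits the phase of the template
#' point it is aligned with; when several template points map to one
#' candidate point, the earliest template phase wins.
#'
#' @param match a `motif_match`.
#' @param template a `motif_template` with non-NULL `phases`.
#' @return character vector of phases, one per candidate row in `[i..j]`.
#' @export
transfer_phases <- function(match, template) {
  if (is.null(template$phases)) return(NULL)
  js <- match$i:match$j
  vapply(js, function(j) {
    tpl <- match$wp_t[match$wp_c == j]
    template$phases[min(tpl)]
  }, character(1))
}

#' Non-maximum suppression of overlapping matches
#'
#' Matches are visited in ascending normalised score; a match is suppressed
#' when it shares at least k-1 cells with an already kept match and their
#' transition frames (midpoint of the matched window when no transition is
#' recorded) differ by at most `window` frames.
#'
#' @param matches list of `motif_match` objects (with `members`).
#' @param window transition-frame tolerance in frames.
#' @return the kept matches, ascending in normalised score.
#' @export
deduplicate_matches <- function(matches, window = 2L) {
  if (!length(matches)) return(matches)
  tf <- vapply(matches, function(m) {
    if (!is.null(m$transition_frame) && !is.na(m$transition_frame)) {
      as.numeric(m$transition_frame)
    } else {
      mean(m$frames)
    }
  }, numeric(1))
  ord <- order(vapply(matches, function(m) m$norm_score, numeric(1)))
  kept <- integer(0)
  for (idx in ord) {
    k <- length(matches[[idx]]$members)
    dup <- FALSE
    for (kk in kept) {
      shared <- length(intersect(matches[[idx]]$members, matches[[kk]]$members))
      if (shared >= k - 1L && abs(tf[idx] - tf[kk]) <= window) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, idx)
  }
  matches[kept]
}
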