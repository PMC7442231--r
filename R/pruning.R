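# Early rejection of candidate tracks before feature extraction and DTW.
# Rules are applied in a fixed order (cheap topology tests first) and the
# first failing rule is recorded per rejected track, so the ledger counts
# partition the rejected set; the retained set itself does not depend on the
# order.

#' Pruning configuration
#'
#' Defaults follow the published filter values: candidate sequences that
#' exist less than 2.5 minutes are discarded, as are T1 candidates whose
#' contracting junction starts (or growing junction ends) below 2 microns;
#' rosette members need at least two in-group neighbours.
#'
#' @param min_persistence_min minimum track duration in minutes.
#' @param min_junction_len_um junction-length threshold for T1 matches (um).
#' @param require_neighbor_exchange reject tracks whose in-group adjacency
#'   never changes.
#' @param allowed_topologies character vector of class ids of which at least
#'   one frame must be an instance; NULL disables the rule.
#' @param reject_enclosed reject groups that fully enclose a non-member cell.
#' @param min_neighbors_in_group minimum in-group degree required of every
#'   member in qualifying frames (rosette rule; 0 disables).
#' @return a `pruning_config` list.
#' @export
pruning_config <- function(min_persistence_min = 2.5,
                           min_junction_len_um = 2.0,
                           require_neighbor_exchange = TRUE,
                           allowed_topologies = NULL,
                           reject_enclosed = TRUE,
                           min_neighbors_in_group = 0L) {
  stopifnot(min_persistence_min >= 0, min_junction_len_um >= 0)
  structure(list(
    min_persistence_min = min_persistence_min,
    min_junction_len_um = min_junction_len_um,
    require_neighbor_exchange = require_neighbor_exchange,
    allowed_topologies = allowed_topologies,
    reject_enclosed = reject_enclosed,
    min_neighbors_in_group = as.integer(min_neighbors_in_group)
  ), class = "pruning_config")
}

#' Default pruning configuration for a motif kind
#'
#' T1 candidates must visit one of the two T1-relevant quartet topologies
#' (diamond or 4-cycle); rosette candidates must keep every member with at
#' least two in-group neighbours.
#'
#' @param motif one of `"t1"`, `"t1_reversal"`, `"rosette5"`, `"rosette6"`.
#' @return a [pruning_config()].
#' @export
default_pruning <- function(motif = c("t1", "t1_reversal", "rosette5", "rosette6")) {
  motif <- match.arg(motif)
  if (motif %in% c("t1", "t1_reversal")) {
    pruning_config(allowed_topologies = unname(t1_allowed_classes()),
                   require_neighbor_exchange = (motif == "t1"))
  } else {
    pruning_config(allowed_topologies = NULL,
                   require_neighbor_exchange = TRUE,
                   min_neighbors_in_group = 2L)
  }
}

# per-group degree check: every member has >= min_deg in-group neighbours in
# at least one frame where the group is connected.
.min_degree_ok <- function(tracks, cfg) {
  k <- tracks$k
  slots <- pair_slots(k)
  n_g <- nrow(tracks$members)
  ok <- logical(n_g)
  degtab <- .epi_cache[[sprintf("mindeg%d", k)]]
  if (is.null(degtab)) {
    n_masks <- 2^nrow(slots)
    degtab <- integer(n_masks)
    for (m in seq_len(n_masks) - 1L) {
      A <- adj_from_mask(m, k)
      degtab[m + 1L] <- min(colSums(A))
    }
    .epi_cache[[sprintf("mindeg%d", k)]] <- degtab
  }
  for (g in seq_len(n_g)) {
    fr <- which(tracks$connected[, g])
    ok[g] <- any(degtab[tracks$class_mask[fr, g] + 1L] >= cfg$min_neighbors_in_group)
  }
  ok
}

#' Prune candidate tracks
#'
#' Applies, in order: (a) allowed-topology visit, (b) rosette in-group degree,
#' (c) enclosed non-member rejection, (d) persistence, (e) neighbour-exchange
#' requirement.  Each rejected track is charged to the first rule it fails.
#'
#' @param tracks a `group_tracks` object.
#' @param seq the `tissue_sequence` the tracks came from.
#' @param cfg a [pruning_config()].
#' @return list with `tracks` (retained `group_tracks`), `keep` (logical over
#'   the input groups) and `ledger` (data.frame key, rule for rejected
#'   tracks).
#' @export
prune_tracks <- function(tracks, seq, cfg = pruning_config()) {
  n_g <- nrow(tracks$members)
  rule <- rep(NA_character_, n_g)
  alive <- rep(TRUE, n_g)

  fail <- function(bad, name) {
    hit <- alive & bad
    rule[hit] <<- name
    alive[hit] <<- FALSE
  }

  # (a) topology visit
  if (!is.null(cfg$allowed_topologies)) {
    k <- tracks$k
    allowed_masks <- .class_masks_for(cfg$allowed_topologies, k)
    visit <- vapply(seq_len(n_g), function(g) {
      fr <- which(tracks$connected[, g])
      any(.canon_vec(tracks$class_mask[fr, g], k) %in% allowed_masks)
    }, logical(1))
    fail(!visit, "topology")
  }
  # (b) rosette degree
  if (cfg$min_neighbors_in_group > 0L) {
    fail(!.min_degree_ok(tracks, cfg), "min_degree")
  }
  # (c) enclosure
  if (cfg$reject_enclosed) {
    enc <- vapply(seq_len(n_g), function(g) {
      if (!alive[g]) return(FALSE)
      fr <- which(tracks$connected[, g])[1L]
      has_enclosed_nonmember(tracks$members[g, ], seq$frames[[fr]])
    }, logical(1))
    fail(enc, "enclosed")
  }
  # (d) persistence
  if (cfg$min_persistence_min > 0) {
    dur <- (tracks$last_frame - tracks$first_frame + 1L) * seq$dt_min
    fail(dur < cfg$min_persistence_min, "persistence")
  }
  # (e) neighbour exchange: some in-group pair toggles adjacency
  if (cfg$require_neighbor_exchange) {
    toggles <- vapply(seq_len(n_g), function(g) {
      m <- tracks$class_mask[, g]
      m <- m[!is.na(m)]
      length(unique(m)) > 1L
    }, logical(1))
    fail(!toggles, "no_neighbor_exchange")
  }

  ledger <- data.frame(key = tracks$keys[!alive], rule = rule[!alive],
                       stringsAsFactors = FALSE)
  list(tracks = tracks_subset(tracks, which(alive)), keep = alive,
       ledger = ledger)
}

.canon_vec <- function(masks, k) {
  vapply(masks, function(m) canonical_mask(m, k), numeric(1))
}

.class_masks_for <- function(class_ids, k) {
  pat <- sprintf("^k%d-c(\\d+)$", k)
  ok <- grepl(pat, class_ids)
  as.numeric(sub(pat, "\\1", class_ids[ok]))
}

#' Junction-length filter for T1-type matches
#'
#' Rejects a matched T1 when the contracting junction starts shorter than the
#' threshold or the growing junction ends shorter than it (strict
#' inequality: a junction of exactly the threshold length is kept).
#'
#' @param match a match record (list with `members`, `i`, `j` frame indices).
#' @param seq the `tissue_sequence`.
#' @param cfg a [pruning_config()].
#' @return TRUE to keep, FALSE to reject, NA when the contracting/growing
#'   junctions cannot be identified (match kept upstream with a warning).
#' @export
junction_length_filter <- function(match, seq, cfg = pruning_config()) {
  jn <- identify_t1_junctions(match$members, seq, match$i, match$j)
  if (is.null(jn)) return(NA)
  init_len <- jn$contract_lengths[1L]
  final_len <- jn$grow_lengths[length(jn$grow_lengths)]
  !(init_len < cfg$min_junction_len_um || final_len < cfg$min_junction_len_um)
}

# Identify the contracting and growing junctions of a quartet within frames
# [i, j]: the member pair adjacent at the start that loses adjacency, and the
# pair that gains it.  Returns NULL if no such toggle exists in the window.
identify_t1_junctions <- function(members, seq, i, j) {
  frames <- seq$frames[i:j]
  prs <- pair_slots(length(members))
  mem <- sort(members)
  adj <- vapply(seq_len(nrow(prs)), function(s) {
    vapply(frames, cells_adjacent, logical(1), mem[prs[s, 1L]], mem[prs[s, 2L]])
  }, logical(length(frames)))
  if (length(frames) == 1L) adj <- matrix(adj, nrow = 1L)
  lost <- which(adj[1L, ] & !adj[nrow(adj), ])
  gained <- which(!adj[1L, ] & adj[nrow(adj), ])
  if (length(lost) != 1L || length(gained) != 1L) return(NULL)
  pair_len <- function(s) {
    a <- mem[prs[s, 1L]]; b <- mem[prs[s, 2L]]
    vapply(frames, function(fr) {
      e <- frame_edge_between(fr, a, b)
      if (is.null(e)) 0 else polyline_length(e$polyline)
    }, numeric(1))
  }
  list(
    pair_lose = mem[prs[lost, ]],
    pair_gain = mem[prs[gained, ]],
    contract_lengths = pair_len(lost),
    grow_lengths = pair_len(gained),
    transition_frame = i - 1L + which(!adj[, lost])[1L]
  )
}
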