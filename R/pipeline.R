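# End-to-end orchestration: enumerate -> prune -> features -> match ->
# classify -> deduplicate -> events, plus validation against a ground-truth
# manifest and generation of labelled validation corpora.

#' Run the full motif-detection pipeline on one tissue sequence
#'
#' @param seq a `tissue_sequence`.
#' @param template a `motif_template`.
#' @param motif motif kind: `"t1"`, `"t1_reversal"`, `"rosette5"`,
#'   `"rosette6"`.
#' @param prune a [pruning_config()] (default: [default_pruning()] for the
#'   motif).
#' @param dtw a [dtw_config()].
#' @param classifier `"1nn"` or `"threshold"`.
#' @param train a [training_set()] (required for `"1nn"` unless `labels`
#'   given).
#' @param labels named label vector used to build the training set from this
#'   run's own matches (alternative to `train`).
#' @param cutoff normalised-score cutoff for the threshold classifier.
#' @param junction_filter apply the 2-micron junction-length filter to
#'   T1-type matches.
#' @return list with `matches` (all scored matches, labelled), `events`
#'   (deduplicated true-labelled matches), `ledger` (rejection records) and
#'   `report` (per-stage counts).
#' @export
run_detect <- function(seq, template, motif = "t1",
                       prune = default_pruning(motif),
                       dtw = dtw_config(),
                       classifier = c("1nn", "threshold"),
                       train = NULL, labels = NULL, cutoff = NULL,
                       junction_filter = TRUE) {
  classifier <- match.arg(classifier)
  k <- template$schema$k
  report <- list(motif = motif, k = k, n_frames = n_frames(seq))

  tracks <- track_groups(seq, k)
  report$n_groups <- nrow(tracks$members)
  report$n_group_frame_slots <- sum(tracks$connected)

  pr <- prune_tracks(tracks, seq, prune)
  kept <- pr$tracks
  report$n_after_prune <- nrow(kept$members)
  report$prune_reduction_groups <-
    1 - report$n_after_prune / max(1L, report$n_groups)
  report$prune_reduction_frame_slots <-
    1 - sum(kept$connected) / max(1L, report$n_group_frame_slots)

  cache <- new.env(parent = emptyenv())
  matches <- list()
  ledger <- pr$ledger
  for (g in seq_len(nrow(kept$members))) {
    mem <- kept$members[g, ]
    cs <- extract_features(mem, seq, template$schema,
                           frames = kept$first_frame[g]:kept$last_frame[g],
                           cache = cache)
    mt <- subsequence_match(template, cs, dtw)
    mt$values_sub <- cs$values[mt$i:mt$j, , drop = FALSE]
    mt$frames <- c(cs$frames[mt$i], cs$frames[mt$j])
    jn <- identify_t1_junctions(mem, seq, mt$frames[1L], mt$frames[2L])
    mt$transition_frame <- if (!is.null(jn)) jn$transition_frame else NA_integer_
    if (junction_filter && motif %in% c("t1", "t1_reversal") && !is.null(jn)) {
      ok <- junction_length_filter(
        list(members = mem, i = mt$frames[1L], j = mt$frames[2L]), seq, prune)
      if (isFALSE(ok)) {
        ledger <- rbind(ledger, data.frame(key = group_key(mem),
                                           rule = "junction_length"))
        next
      }
    }
    matches[[length(matches) + 1L]] <- mt
  }
  report$n_matched <- length(matches)

  if (classifier == "1nn") {
    if (is.null(train)) {
      if (is.null(labels)) stop("1NN classification needs 'train' or 'labels'")
      train <- training_set(matches, labels)
    }
    matches <- classify_1nn(matches, train, dtw)
  } else {
    if (is.null(cutoff)) stop("threshold classification needs 'cutoff'")
    matches <- threshold_classifier(matches, cutoff)
  }
  report$n_true <- sum(vapply(matches, function(m) m$label == "true", logical(1)))

  events <- deduplicate_matches(
    Filter(function(m) m$label == "true", matches))
  report$n_events <- length(events)
  report$config_hash <- .config_hash(list(motif = motif, prune = prune,
                                          dtw = dtw, classifier = classifier,
                                          cutoff = cutoff))
  list(matches = matches, events = events, ledger = ledger, report = report)
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Score detections against a ground-truth manifest
#'
#' Candidate-group-level confusion: a scripted motif counts as detected (TP)
#' when an event with exactly its member set is reported; a distractor counts
#' as a false positive when its candidate group is reported.
#'
#' @param events list of true-labelled `motif_match` events (from
#'   [run_detect()]).
#' @param truth ground-truth data.frame from [simulate_tissue()].
#' @param motif the motif type that was searched for.
#' @return list with `tp`, `fn`, `fp`, `tn`, `sensitivity`, `specificity`
#'   (percent; NA when undefined).
#' @export
run_validate <- function(events, truth, motif = "t1") {
  det_keys <- vapply(events, function(e) group_key(e$members), character(1))
  true_rows <- truth[truth$type == motif, , drop = FALSE]
  distract_rows <- truth[truth$type != motif & !is.na(truth$members) &
                           nzchar(truth$members), , drop = FALSE]
  tp <- sum(true_rows$members %in% det_keys)
  fn <- nrow(true_rows) - tp
  fp <- sum(distract_rows$members %in% det_keys)
  tn <- nrow(distract_rows) - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# -- validation corpus -------------------------------------------------------

# Plan spatially disjoint scripted events on a rows x cols hexagonal grid:
# picks interior junctions whose quartets (and their immediate surroundings)
# do not overlap, and staggers onsets.
plan_scripted_events <- function(rows, cols, n_t1, n_distractor, n_frames,
                                 edge_len = 3, seed = 1) {
  st <- hex_lattice(rows, cols, edge_len, 0)
  ed <- state_edges(st)
  rim <- unique(stats::na.omit(ed$c1[is.na(ed$c2)]))
  inter <- ed[!is.na(ed$c2), , drop = FALSE]
  nb_of <- function(cc) {
    stats::na.omit(c(inter$c2[inter$c1 == cc], inter$c1[inter$c2 == cc]))
  }
  cand <- list()
  for (r in seq_len(nrow(inter))) {
    a <- inter$c1[r]; b <- inter$c2[r]
    common <- intersect(nb_of(a), nb_of(b))
    quartet <- c(a, b, common)
    if (length(quartet) != 4L) next
    if (any(quartet %in% rim)) next
    cand[[length(cand) + 1L]] <- list(pair = c(a, b), quartet = quartet,
                                      zone = unique(c(quartet,
                                                      unlist(lapply(quartet, nb_of)))))
  }
  n_events <- n_t1 + n_distractor
  if (length(cand) < n_events) {
    stop("grid too small for the requested number of disjoint events")
  }
  ord <- sample(seq_along(cand))
  chosen <- list()
  used_cells <- integer(0)
  # first pass keeps quartets out of each other's mechanical surroundings;
  # a second pass fills remaining slots requiring only disjoint quartets
  for (strict in c(TRUE, FALSE)) {
    for (i in ord) {
      if (length(chosen) == n_events) break
      if (any(cand[[i]]$quartet %in% used_cells)) next
      if (strict && length(chosen) &&
          any(vapply(chosen, function(ch) any(cand[[i]]$quartet %in% ch$zone),
                     logical(1)))) next
      chosen[[length(chosen) + 1L]] <- cand[[i]]
      used_cells <- c(used_cells, cand[[i]]$quartet)
    }
  }
  if (length(chosen) < n_events) {
    stop("could not place the requested number of disjoint events")
  }
  onset_window <- max(2L, n_frames - 16L)
  onsets <- 3L + (seq_len(n_events) - 1L) %% onset_window
  onsets <- sample(onsets)
  evs <- vector("list", n_events)
  types <- sample(c(rep("t1", n_t1), rep("distractor", n_distractor)))
  d_alt <- 0L
  for (i in seq_len(n_events)) {
    p <- chosen[[i]]$pair
    if (types[i] == "t1") {
      evs[[i]] <- script_t1(p[1L], p[2L], onsets[i])
    } else {
      d_alt <- d_alt + 1L
      evs[[i]] <- if (d_alt %% 3L == 0L) {
        script_dilation(p[1L], onsets[i])
      } else if (d_alt %% 3L == 1L) {
        script_pulse(p[1L], p[2L], onsets[i])
      } else {
        script_reversal(p[1L], p[2L], onsets[i])
      }
    }
  }
  evs
}

#' Generate a labelled validation corpus
#'
#' Simulates several tissues per seed, each carrying scripted T1 events plus
#' distractor deformations (pulsatile contractions, abortive reversals,
#' division-like area changes), and returns the simulations together with
#' the ground-truth manifest used for sensitivity/specificity scoring.
#'
#' @param n_true total number of scripted T1 events.
#' @param n_distractor total number of scripted distractors.
#' @param seeds integer vector of seeds; simulations are spread evenly over
#'   them.
#' @param events_per_sim scripted T1s (and distractors) per simulation.
#' @param rows,cols,n_frames simulation size (see [sim_config()]).
#' @return list of `list(tissue, truth, seed)` per simulation; the manifest
#'   is the row-bound `truth` with a `sim` column.
#' @export
make_validation_set <- function(n_true = 100, n_distractor = 100,
                                seeds = 1:5, events_per_sim = 5,
                                rows = 12, cols = 12, n_frames = 40) {
  n_sims <- ceiling(n_true / events_per_sim)
  per_sim_d <- ceiling(n_distractor / n_sims)
  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    seed <- seeds[((s - 1L) %% length(seeds)) + 1L]
    sim_seed <- seed * 1000L + s
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(sim_seed)
    evs <- plan_scripted_events(rows, cols, events_per_sim, per_sim_d,
                                n_frames, seed = sim_seed)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cfg <- sim_config(rows = rows, cols = cols, n_frames = n_frames,
                      scripted_events = evs, seed = sim_seed)
    out <- simulate_tissue(cfg)
    out$truth$sim <- s
    out$seed <- sim_seed
    sims[[s]] <- out
  }
  sims
}

#' Run the synthetic validation experiment
#'
#' Generates a validation corpus of scripted T1 events plus distractors
#' ([make_validation_set()]), builds the search template from one held-out
#' simulated event, performs a single labelling round on the first
#' simulation (labels taken from its ground-truth manifest, mimicking a user
#' annotating the sorted candidate sheet), classifies every simulation with
#' the 1NN rule and scores detections against the manifest.
#'
#' @inheritParams make_validation_set
#' @param n_label_true,n_label_false training labels contributed by the
#'   labelling round.
#' @param template_seed seed of the held-out template simulation.
#' @return list with `sensitivity`, `specificity` (percent), the pooled
#'   confusion counts, `n_true_events`, `n_distractors` and per-simulation
#'   details.
#' @export
validation_experiment <- function(n_true = 100, n_distractor = 100,
                                  seeds = 1:5, events_per_sim = 5,
                                  rows = 12, cols = 12, n_frames = 40,
                                  n_label_true = 10, n_label_false = 10,
                                  template_seed = 990) {
  template <- t1_template_from_simulation(seed = template_seed)
  sims <- make_validation_set(n_true, n_distractor, seeds, events_per_sim,
                              rows, cols, n_frames)
  # labelling round on the first simulation: annotate the sorted sheet
  first <- run_detect(sims[[1L]]$tissue, template, motif = "t1",
                      classifier = "threshold", cutoff = Inf)
  m1 <- first$matches
  ord <- order(vapply(m1, function(m) m$norm_score, numeric(1)))
  true_keys <- sims[[1L]]$truth$members[sims[[1L]]$truth$type == "t1"]
  labels <- character(0)
  nt <- 0L; nf <- 0L
  for (i in ord) {
    key <- group_key(m1[[i]]$members)
    is_true <- key %in% true_keys
    if (is_true && nt < n_label_true) {
      labels[[match_key(m1[[i]])]] <- "true"; nt <- nt + 1L
    } else if (!is_true && nf < n_label_false) {
      labels[[match_key(m1[[i]])]] <- "false"; nf <- nf + 1L
    }
    if (nt >= n_label_true && nf >= n_label_false) break
  }
  train <- training_set(m1, labels)
  tp <- fn <- fp <- tn <- 0L
  per_sim <- vector("list", length(sims))
  for (s in seq_along(sims)) {
    det <- run_detect(sims[[s]]$tissue, template, motif = "t1",
                      classifier = "1nn", train = train)
    val <- run_validate(det$events, sims[[s]]$truth, motif = "t1")
    tp <- tp + val$tp; fn <- fn + val$fn
    fp <- fp + val$fp; tn <- tn + val$tn
    # transition-frame accuracy of detected events
    det_keys <- vapply(det$events, function(e) group_key(e$members), character(1))
    tr <- sims[[s]]$truth
    tr_t1 <- tr[tr$type == "t1", ]
    hit <- match(tr_t1$members, det_keys)
    trans_err <- ifelse(is.na(hit), NA_real_,
                        vapply(seq_along(hit), function(i) {
                          if (is.na(hit[i])) return(NA_real_)
                          tf <- det$events[[hit[i]]]$transition_frame
                          if (is.null(tf) || is.na(tf)) return(NA_real_)
                          abs(tf - tr_t1$transition_frame[i])
                        }, numeric(1)))
    per_sim[[s]] <- list(report = det$report, validate = val,
                         transition_error = trans_err)
  }
  list(
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, fp = fp, tn = tn,
    n_true_events = tp + fn, n_distractors = tn + fp,
    transition_errors = unlist(lapply(per_sim, `[[`, "transition_error")),
    per_sim = per_sim,
    template = template
  )
}

#' Build a canonical T1 template from a dedicated simulation
#'
#' Runs one single-T1 simulation and converts the scripted event into a
#' phase-labelled quartet template spanning contraction, the neighbour
#' exchange and growth.
#'
#' @param seed simulation seed.
#' @param mode feature pair-order mode (see [feature_schema()]).
#' @param pad frames kept before onset and after the growth phase.
#' @return a `motif_template`.
#' @export
t1_template_from_simulation <- function(seed = 990, mode = "sorted", pad = 2L) {
  cfg <- sim_config(rows = 6, cols = 6, n_frames = 26,
                    scripted_events = list(script_t1(15L, 16L, 5L)),
                    seed = seed)
  out <- simulate_tissue(cfg)
  tr <- out$truth[out$truth$type == "t1", ][1L, ]
  frames <- max(1L, tr$onset_frame - pad):min(n_frames(out$tissue),
                                              tr$end_frame + pad)
  phases <- ifelse(frames < tr$transition_frame, "contracting",
                   ifelse(frames == tr$transition_frame, "transition",
                          "growing"))
  template_from_example(out$tissue, key_to_members(tr$members), frames,
                        feature_schema("quartet_pairdist", mode = mode),
                        phases = phases)
}
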