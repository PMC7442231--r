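# Separating true from false detections.  The primary route is the
# 1-nearest-neighbour rule under the DTW dissimilarity between matched
# feature subsequences, trained from file-based labelling rounds; a plain
# score-cutoff classifier is provided as the baseline it replaces.

#' Assemble a training set from labelled matches
#'
#' @param matches list of `motif_match` objects.
#' @param labels named character vector (`"true"` / `"false"`), names =
#'   match keys as produced by [match_key()].
#' @return a `training_set`: list of entries with `key`, `label`, `values`
#'   (the matched feature subsequence).
#' @export
training_set <- function(matches, labels) {
  bad <- setdiff(unique(labels), c("true", "false"))
  if (length(bad)) stop("unknown label token(s): ", paste(bad, collapse = ", "))
  keys <- vapply(matches, match_key, character(1))
  entries <- list()
  for (i in seq_along(matches)) {
    if (!keys[i] %in% names(labels)) next
    entries[[length(entries) + 1L]] <- list(
      key = keys[i],
      label = unname(labels[[keys[i]]]),
      values = matches[[i]]$values_sub
    )
  }
  structure(entries, class = "training_set")
}

#' Key identifying a match (member set + matched window)
#' @param match a `motif_match`.
#' @return character key, e.g. `"3+7+12+15@5-18"`.
#' @export
match_key <- function(match) {
  sprintf("%s@%d-%d", paste(sort(match$members), collapse = "+"),
          match$frames[1L], match$frames[2L])
}

# Normalised DTW distance between two feature subsequences: full alignment
# score divided by warping-path length (length-invariant); `normalize =
# FALSE` gives the raw alignment score.
.nn_distance <- function(a, b, cfg, normalize = TRUE) {
  sc <- tryCatch(dtw_score(a, b, cfg), error = function(e) NULL)
  if (is.null(sc)) return(Inf)
  if (normalize) sc$norm_score else sc$raw_score
}

#' 1-nearest-neighbour classification of matches
#'
#' Each unlabelled match inherits the label of its most similar training
#' entry under the normalised DTW distance between matched subsequences.
#' Distance ties are resolved conservatively towards `"false"`, then by
#' training order.
#'
#' @param matches list of `motif_match` objects carrying `values_sub` (the
#'   matched feature subsequence; filled by the pipeline).
#' @param train a [training_set()] with at least one entry of each label.
#' @param cfg a [dtw_config()].
#' @param normalize use path-length-normalised DTW distances (default) or
#'   raw alignment scores.
#' @return the matches with `label` and `nn_distance` filled in.
#' @export
classify_1nn <- function(matches, train, cfg = dtw_config(),
                         normalize = TRUE) {
  if (!length(train)) {
    stop("empty training set: run a labelling round first (see labeling_round)")
  }
  labs <- vapply(train, function(e) e$label, character(1))
  if (!all(c("true", "false") %in% labs)) {
    warning("training set lacks one of the labels; all matches will inherit ",
            "the available label")
  }
  # conservative tie-break: consider 'false' entries first, then training order
  ord <- order(labs != "false")
  train <- train[ord]; labs <- labs[ord]
  lapply(matches, function(mt) {
    d <- vapply(train, function(e) {
      .nn_distance(mt$values_sub, e$values, cfg, normalize)
    }, numeric(1))
    best <- which.min(d)   # first minimum: 'false' entries win ties
    mt$label <- labs[best]
    mt$nn_distance <- d[best]
    mt$nn_key <- train[[best]]$key
    mt
  })
}

#' File-based labelling round
#'
#' Replaces an interactive labelling interface: the sorted candidate sheet is
#' written for the user to annotate, and previously annotated label files are
#' merged (later files override earlier ones, duplicate keys: last wins).
#'
#' @param matches list of `motif_match` objects, any order.
#' @param labels_files character vector of CSV paths with columns
#'   `match_key,label`; missing files are skipped.
#' @param sheet_path optional path; when given, the candidate sheet (sorted
#'   ascending by normalised score, with current labels) is written there.
#' @return list with `train` (a [training_set()]) and `labels` (merged named
#'   vector).
#' @export
labeling_round <- function(matches, labels_files = character(0),
                           sheet_path = NULL) {
  labels <- character(0)
  for (f in labels_files) {
    if (!file.exists(f)) next
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("match_key", "label") %in% names(df))) {
      stop("label file ", f, " must have columns match_key,label")
    }
    bad <- which(!df$label %in% c("true", "false"))
    if (length(bad)) {
      stop(sprintf("unknown label token '%s' in %s at line %d",
                   df$label[bad[1L]], f, bad[1L] + 1L))
    }
    for (r in seq_len(nrow(df))) labels[[df$match_key[r]]] <- df$label[r]
  }
  ord <- order(vapply(matches, function(m) m$norm_score, numeric(1)))
  if (!is.null(sheet_path)) {
    keys <- vapply(matches[ord], match_key, character(1))
    sheet <- data.frame(
      match_key = keys,
      norm_score = vapply(matches[ord], function(m) m$norm_score, numeric(1)),
      label = ifelse(keys %in% names(labels), labels[keys], ""),
      stringsAsFactors = FALSE
    )
    utils::write.csv(sheet, sheet_path, row.names = FALSE)
  }
  list(train = training_set(matches, labels), labels = labels)
}

#' Score-cutoff baseline classifier
#'
#' Labels a match `"true"` iff its normalised DTW score is at most `cutoff`.
#' Provided as the manual-threshold baseline that nearest-neighbour
#' classification replaces.
#'
#' @param matches list of `motif_match` objects.
#' @param cutoff normalised-score cutoff.
#' @return the matches with `label` filled in.
#' @export
threshold_classifier <- function(matches, cutoff) {
  lapply(matches, function(mt) {
    mt$label <- if (mt$norm_score <= cutoff) "true" else "false"
    mt
  })
}
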