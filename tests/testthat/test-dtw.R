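test_that("dtw matches hand-computed and degenerate cases", {
  expect_equal(dtw_score(matrix(1:5), matrix(1:5))$raw_score, 0)
  # T=[0,0], S=[0,1]: 3-cell DP table gives 1.0
  expect_equal(dtw_score(matrix(c(0, 0)), matrix(c(0, 1)))$raw_score, 1)
  # identical series align on the diagonal
  sc <- dtw_score(matrix(1:5), matrix(1:5))
  expect_equal(sc$wp_t, 1:5)
  expect_equal(sc$wp_c, 1:5)
})

test_that("dtw equals the brute-force all-paths oracle", {
  set.seed(7)
  for (rep in 1:150) {
    m <- sample(2:6, 1); n <- sample(2:6, 1); d <- sample(1:3, 1)
    TV <- matrix(rnorm(m * d), m)
    SV <- matrix(rnorm(n * d), n)
    R <- sample(2:4, 1)
    oracle <- brute_dtw(cost_of(TV, SV), R)
    got <- tryCatch(dtw_score(TV, SV, dtw_config(max_repeat = R))$raw_score,
                    error = function(e) Inf)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("subsequence matching recovers exact and time-warped embeddings", {
  set.seed(9)
  T <- matrix(sin(1:8), ncol = 1)
  C <- rbind(matrix(9 + runif(5), ncol = 1), T, matrix(-9 + runif(4), ncol = 1))
  mt <- subsequence_match(T, C)
  expect_equal(c(mt$i, mt$j), c(6, 13))
  expect_equal(mt$norm_score, 0)
  # half-speed candidate: every frame duplicated, still a perfect match
  C2 <- T[rep(1:8, each = 2), , drop = FALSE]
  mt2 <- subsequence_match(T, C2, dtw_config(max_repeat = 2))
  expect_equal(mt2$norm_score, 0)
  expect_true(any(table(mt2$wp_t) == 2))  # template points repeated
})

test_that("warping paths always satisfy their step and repetition bounds", {
  set.seed(13)
  for (rep in 1:40) {
    m <- sample(3:10, 1); n <- sample(6:20, 1)
    TV <- matrix(rnorm(m * 2), m)
    CV <- matrix(rnorm(n * 2), n)
    R <- sample(2:3, 1)
    mt <- subsequence_match(TV, CV, dtw_config(max_repeat = R))
    expect_equal(mt$wp_t[1], 1)
    expect_equal(mt$wp_t[length(mt$wp_t)], m)
    expect_true(all(diff(mt$wp_t) %in% 0:1))
    expect_true(all(diff(mt$wp_c) %in% 0:1))
    expect_lte(max(table(mt$wp_t)), R)
    expect_lte(max(table(mt$wp_c)), R)
    # path pairs are consistent with the reported window
    expect_equal(mt$wp_c[1], mt$i)
    expect_equal(mt$wp_c[length(mt$wp_c)], mt$j)
  }
})

test_that("appending candidate frames never worsens the best match", {
  set.seed(17)
  TV <- matrix(rnorm(5), ncol = 1)
  CV <- matrix(rnorm(8), ncol = 1)
  prev <- subsequence_match(TV, CV)$norm_score
  for (extra in 1:5) {
    CV <- rbind(CV, rnorm(1))
    cur <- subsequence_match(TV, CV)$norm_score
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("phase labels transfer along the warping path", {
  tpl <- list(values = matrix(c(3, 2, 1, 0, 1, 2), ncol = 1),
              phases = c("contracting", "contracting", "contracting",
                         "transition", "growing", "growing"),
              schema = feature_schema("rosette_maxpairdist", k = 5))
  class(tpl) <- "motif_template"
  # identity alignment copies labels
  mt <- subsequence_match(tpl, tpl$values)
  expect_equal(mt$phases, tpl$phases)
  # half-speed candidate, full alignment: with the repetition cap at 2 every
  # template point must cover exactly two frames, so each phase doubles
  C2 <- tpl$values[rep(1:6, each = 2), , drop = FALSE]
  sc <- dtw_score(tpl$values, C2, dtw_config(max_repeat = 2))
  mt2 <- structure(list(i = 1L, j = nrow(C2), wp_t = sc$wp_t, wp_c = sc$wp_c),
                   class = "motif_match")
  ph2 <- transfer_phases(mt2, tpl)
  expect_equal(table(ph2)[names(table(tpl$phases))],
               2 * table(tpl$phases), ignore_attr = TRUE)
})

test_that("phase transfer brackets the simulated neighbour exchange", {
  sim <- get_t1_sim()
  tpl <- get_t1_template()
  tracks <- track_groups(sim$tissue, 4)
  pr <- prune_tracks(tracks, sim$tissue, default_pruning("t1"))
  g <- which(pr$tracks$keys == sim$truth$members[1])
  cs <- extract_features(pr$tracks$members[g, ], sim$tissue, tpl$schema)
  mt <- subsequence_match(tpl, cs)
  lab <- mt$phases
  frames <- cs$frames[mt$i:mt$j]
  trans_lab <- frames[lab == "transition"]
  expect_true(any(abs(trans_lab - sim$truth$transition_frame[1]) <= 1))
})

test_that("non-maximum suppression keeps distinct events only", {
  mk <- function(members, score, tf) {
    structure(list(members = members, norm_score = score,
                   transition_frame = tf, frames = c(tf - 3, tf + 3)),
              class = "motif_match")
  }
  # identical duplicates collapse
  out <- deduplicate_matches(list(mk(1:4, 0.1, 10), mk(1:4, 0.2, 10)))
  expect_length(out, 1)
  expect_equal(out[[1]]$norm_score, 0.1)
  # disjoint groups both kept
  out2 <- deduplicate_matches(list(mk(1:4, 0.1, 10), mk(5:8, 0.2, 10)))
  expect_length(out2, 2)
  # sharing k-1 cells but far apart in time: both kept
  out3 <- deduplicate_matches(list(mk(1:4, 0.1, 10), mk(c(1:3, 9), 0.2, 20)))
  expect_length(out3, 2)
  # sharing only 2 of 4 cells at the same time: both kept
  out4 <- deduplicate_matches(list(mk(1:4, 0.1, 10), mk(c(1, 2, 9, 10), 0.2, 10)))
  expect_length(out4, 2)
})
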