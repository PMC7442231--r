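# Small synthetic match objects: V-shaped "event" profiles vs noise.
mk_match <- function(values, members, i = 1L) {
  structure(list(members = members, values_sub = matrix(values, ncol = 1),
                 i = i, j = i + length(values) - 1L,
                 frames = c(i, i + length(values) - 1L),
                 norm_score = stats::runif(1), label = "unlabeled"),
            class = "motif_match")
}

vshape <- function(depth = 3, jitter = 0) {
  v <- c(seq(depth, 0, length.out = 5), seq(depth / 4, depth, length.out = 4))
  v + stats::rnorm(length(v), 0, jitter)
}

test_that("1NN is consistent on its training set and copies labels", {
  set.seed(31)
  m_true <- mk_match(vshape(), 1:4)
  m_false <- mk_match(runif(9, 2, 3), 5:8)
  labels <- stats::setNames(c("true", "false"),
                            c(match_key(m_true), match_key(m_false)))
  train <- training_set(list(m_true, m_false), labels)
  out <- classify_1nn(list(m_true, m_false), train)
  expect_equal(vapply(out, function(m) m$label, character(1)),
               c("true", "false"))
  expect_equal(out[[1]]$nn_distance, 0)
  # an unlabelled copy of a 'true' entry is labelled true at distance 0
  copycat <- mk_match(vshape(), 10:13)
  copycat$values_sub <- m_true$values_sub
  expect_equal(classify_1nn(list(copycat), train)[[1]]$label, "true")
})

test_that("single training entry labels everything; empty set errors", {
  set.seed(32)
  m_true <- mk_match(vshape(), 1:4)
  train <- training_set(list(m_true),
                        stats::setNames("true", match_key(m_true)))
  cands <- list(mk_match(runif(7), 11:14), mk_match(vshape(), 15:18))
  expect_warning(out <- classify_1nn(cands, train), "lacks")
  expect_true(all(vapply(out, function(m) m$label, character(1)) == "true"))
  expect_error(classify_1nn(cands, training_set(list(), character(0))),
               "labelling round")
})

test_that("1NN separates simulated events from noise and is deterministic", {
  set.seed(33)
  train_m <- c(lapply(1:10, function(i) mk_match(vshape(jitter = 0.1), 1:4)),
               lapply(1:10, function(i) mk_match(runif(9, 1.5, 3.5), 5:8)))
  labels <- stats::setNames(rep(c("true", "false"), each = 10),
                            vapply(train_m, match_key, character(1)))
  train <- training_set(train_m, labels)
  test_m <- c(lapply(1:25, function(i) mk_match(vshape(jitter = 0.15), 20:23)),
              lapply(1:25, function(i) mk_match(runif(9, 1.5, 3.5), 30:33)))
  out <- classify_1nn(test_m, train)
  got <- vapply(out, function(m) m$label, character(1))
  acc <- mean(got == rep(c("true", "false"), each = 25))
  expect_gte(acc, 0.95)
  out2 <- classify_1nn(test_m, train)
  expect_identical(got, vapply(out2, function(m) m$label, character(1)))
})

test_that("labelling rounds merge files with last-wins and validate tokens", {
  set.seed(34)
  ms <- lapply(1:4, function(i) mk_match(vshape(jitter = 0.2), i * 4 + 1:4))
  keys <- vapply(ms, match_key, character(1))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(match_key = keys[1:2],
                              label = c("true", "false")), f1, row.names = FALSE)
  utils::write.csv(data.frame(match_key = keys[2], label = "true"), f2,
                   row.names = FALSE)
  lr <- labeling_round(ms, c(f1, f2), sheet_path = tempfile(fileext = ".csv"))
  expect_equal(unname(lr$labels[keys[2]]), "true")  # later round overrides
  expect_length(lr$train, 2)
  # empty label set leaves matches untrained
  lr0 <- labeling_round(ms, character(0))
  expect_length(lr0$train, 0)
  # unknown token errors with a line number
  fbad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(match_key = keys[1], label = "maybe"), fbad,
                   row.names = FALSE)
  expect_error(labeling_round(ms, fbad), "line 2")
})

test_that("threshold baseline behaves at its extremes", {
  set.seed(35)
  ms <- lapply(1:6, function(i) mk_match(runif(9), i * 4 + 1:4))
  for (i in seq_along(ms)) ms[[i]]$norm_score <- i / 10
  lab0 <- vapply(threshold_classifier(ms, 0), function(m) m$label, character(1))
  expect_true(all(lab0 == "false"))
  labInf <- vapply(threshold_classifier(ms, Inf), function(m) m$label,
                   character(1))
  expect_true(all(labInf == "true"))
  lab3 <- vapply(threshold_classifier(ms, 0.3), function(m) m$label,
                 character(1))
  expect_equal(sum(lab3 == "true"), 3)
})
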