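test_that("polygonising a toy 3x3 tissue recovers walls and adjacency", {
  L <- toy_label_grid()
  fr <- polygonize_frame(L, pixel_size = 1, simplify_tol = 1)
  A <- frame_adjacency_matrix(fr)
  # centre cell touches exactly its 4 side neighbours
  expect_equal(sum(A["5", ]), 4)
  # diagonal cells meet only at a branch point: not adjacent
  expect_false(A["1", "5"])
  expect_false(A["3", "5"])
  expect_equal(length(fr$edges), 12)
  # straight shared walls simplify to their 2 endpoints
  e <- frame_edge_between(fr, 1, 2)
  expect_equal(nrow(e$polyline), 2)
  # all but the centre cell touch the raster border
  bnd <- vapply(fr$cells, function(cl) cl$is_boundary_cell, logical(1))
  expect_equal(sum(bnd), 8)
  expect_false(bnd[["5"]])
})

test_that("adjacency is symmetric and irreflexive in every simulated frame", {
  sim <- get_t1_sim()
  for (fr in sim$tissue$frames[c(1, 5, 10, 25)]) {
    A <- frame_adjacency_matrix(fr)
    expect_true(all(A == t(A)))
    expect_true(all(!diag(A)))
  }
})

test_that("empty or degenerate rasters are rejected", {
  expect_error(polygonize_frame(matrix(0L, 10, 10)), "no positive labels")
  expect_error(polygonize_frame(matrix(1L, 2, 2)), "3 x 3")
})

test_that("thick membranes trigger the thinning warning", {
  L <- matrix(0L, 12, 12)
  L[2:5, 2:11] <- 1L
  L[9:11, 2:11] <- 2L  # 3-pixel-thick gap between the cells
  expect_warning(polygonize_frame(L, pixel_size = 1), "thinning")
})

test_that("edge_length sums junction segment lengths", {
  e <- list(polyline = rbind(c(0, 0), c(3, 4)))
  expect_equal(edge_length(e), 5)
})

test_that("index propagation keeps, renumbers and asserts correctly", {
  L <- toy_label_grid()
  # identity: all indices preserved
  expect_identical(propagate_indices(L, L), L)
  # shifted by 1 pixel: well above half-overlap, indices preserved
  L2 <- matrix(0L, 17, 17)
  L2[, 2:17] <- L[, 1:16]
  expect_equal(sort(unique(propagate_indices(L, L2)[L2 > 0])), 1:9)
  # a new cell with no qualifying overlap gets a fresh maximal index
  L3 <- L
  L3[L3 == 5L] <- 0L
  L3[8:10, 8:10] <- 99L  # small blob, < half of old cell 5's area
  out <- propagate_indices(L, L3)
  expect_equal(max(out), 10L)        # max(existing) + 1
  expect_true(all(out[L3 == 99L] == 10L))
})

test_that("index propagation is idempotent and conserves counts", {
  sim <- get_quiet_sim()
  M <- render_labels(sim$tissue$frames[[1]], pixel_size = 0.2405)
  expect_identical(propagate_indices(M, M), M)
  n1 <- length(unique(M[M > 0]))
  M2 <- render_labels(sim$tissue$frames[[2]], pixel_size = 0.2405)
  out <- propagate_indices(M, M2)
  expect_equal(length(unique(out[out > 0])), n1)
})

test_that("tissue JSON round-trip is lossless", {
  sim <- get_quiet_sim()
  path <- tempfile(fileext = ".json")
  write_tissue(sim$tissue, path)
  back <- read_tissue(path)
  expect_equal(n_frames(back), n_frames(sim$tissue))
  expect_equal(back$pixel_size, sim$tissue$pixel_size)
  for (f in seq_len(n_frames(back))) {
    a <- sim$tissue$frames[[f]]; b <- back$frames[[f]]
    expect_equal(b$time, a$time)
    expect_equal(names(b$cells), names(a$cells))
    expect_equal(b$cells[["13"]]$boundary, a$cells[["13"]]$boundary)
    expect_equal(frame_adjacency_pairs(b), frame_adjacency_pairs(a))
  }
  # gz round trip
  pgz <- tempfile(fileext = ".json.gz")
  write_tissue(sim$tissue, pgz)
  expect_equal(frame_adjacency_pairs(read_tissue(pgz)$frames[[1]]),
               frame_adjacency_pairs(sim$tissue$frames[[1]]))
  # empty file is a format error
  empty <- tempfile(fileext = ".json")
  file.create(empty)
  expect_error(read_tissue(empty), "format error")
})

test_that("render -> polygonise round trip recovers adjacency and areas", {
  sim <- get_quiet_sim()
  f1 <- sim$tissue$frames[[1]]
  M <- render_labels(f1, pixel_size = 0.2405)
  fr2 <- polygonize_frame(M, pixel_size = 0.2405)
  ids <- frame_cell_ids(f1)
  A1 <- frame_adjacency_matrix(f1, ids)
  A2 <- frame_adjacency_matrix(fr2, ids)
  expect_identical(A1, A2)
  # interior-cell areas within 5% (border-cell polygons are pixel contours)
  bnd <- vapply(f1$cells, function(cl) cl$is_boundary_cell, logical(1))
  for (id in names(f1$cells)[!bnd]) {
    a1 <- polygon_area(f1$cells[[id]]$boundary)
    a2 <- polygon_area(fr2$cells[[id]]$boundary)
    expect_lt(abs(a2 - a1) / a1, 0.05)
  }
})

test_that("TIFF stack ingestion reproduces simulator adjacency", {
  skip_if_not_installed("tiff")
  sim <- get_quiet_sim()
  stack <- render_labels(sim$tissue, pixel_size = 0.2405)
  path <- tempfile(fileext = ".tif")
  write_label_stack(stack, path)
  seq2 <- read_tissue(path, pixel_size = 0.2405)
  expect_equal(n_frames(seq2), n_frames(sim$tissue))
  ids <- frame_cell_ids(sim$tissue$frames[[1]])
  agree <- 0; total <- 0
  for (f in seq_len(n_frames(seq2))) {
    A1 <- frame_adjacency_matrix(sim$tissue$frames[[f]], ids)
    A2 <- frame_adjacency_matrix(seq2$frames[[f]], ids)
    agree <- agree + sum(A1 == A2); total <- total + length(A1)
  }
  expect_gte(agree / total, 0.99)
})
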