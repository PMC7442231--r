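test_that("motif frequency reproduces hand-computed toy values", {
  mkc <- function(id, bnd) list(id = id, boundary = diag(2),
                                is_boundary_cell = bnd)
  fr <- epi_frame(lapply(1:12, function(i) mkc(i, i > 10)), list(), 0)
  # one event with 3/4 interior cells + one fully interior, |C| = 10,
  # dt = 0.5 min: 100 * (1/4) * ((3 + 4)/10) / 0.5 = 35
  ev <- list(c(1, 2, 3, 11), c(4, 5, 6, 7))
  expect_equal(motif_frequency(ev, fr, dt_min = 0.5, k = 4), 35)
  # no events
  expect_equal(motif_frequency(list(), fr, dt_min = 0.5, k = 4), 0)
  # one fully interior event in a 100-interior-cell frame, dt = 1
  fr2 <- epi_frame(lapply(1:101, function(i) mkc(i, i > 100)), list(), 0)
  expect_equal(motif_frequency(list(1:4), fr2, dt_min = 1, k = 4), 1)
  # an event whose cells are all boundary contributes nothing
  expect_equal(motif_frequency(list(c(11, 12, 11, 12)), fr, 1, 4), 0)
  # linear in event count, inverse in dt
  f1 <- motif_frequency(ev, fr, 1, 4)
  expect_equal(motif_frequency(c(ev, ev), fr, 1, 4), 2 * f1)
  expect_equal(motif_frequency(ev, fr, 2, 4), f1 / 2)
  # undefined without interior cells
  fr3 <- epi_frame(lapply(1:3, function(i) mkc(i, TRUE)), list(), 0)
  expect_error(motif_frequency(ev, fr3, 1, 4), "undefined")
})

test_that("kinetics pipeline is exact on noiseless linear traces", {
  tt <- seq(0, 12, by = 0.5)
  kk <- junction_kinetics(6 - 0.5 * tt, tt, "contracting")
  expect_equal(unique(round(kk$rates, 9)), -0.5)
  expect_equal(diff(kk$times[1:2]), 0.5)  # resampled to 30 s
  # constant trace: all rates zero
  k0 <- junction_kinetics(rep(4, 20), seq(0, 9.5, by = 0.5), "contracting")
  expect_true(all(k0$rates == 0))
  # truncation: contracting trace stops at its first zero
  lens <- c(3, 2, 1, 0, 0, 2, 3)
  tr <- epimotifs:::truncate_junction_trace(lens, 0:6, "contracting")
  expect_equal(tr$lengths, c(3, 2, 1, 0))
  # growing trace starts at persistent growth (>= 2 consecutive positives)
  g <- epimotifs:::truncate_junction_trace(c(0, 1, 0, 1, 2, 3), 0:5, "growing")
  expect_equal(g$lengths, c(1, 2, 3))
  # too-short traces are skipped with a warning
  expect_warning(out <- junction_kinetics(c(1, 0), c(0, 0.5), "contracting"),
                 "skipped")
  expect_null(out)
})

test_that("event-averaged rates keep only full 10-minute traces", {
  tt_long <- seq(0, 15, by = 0.5)
  tt_short <- seq(0, 5, by = 0.5)
  ks <- list(
    junction_kinetics(15 - 1 * tt_long, tt_long, "contracting"),
    junction_kinetics(15 - 0.5 * tt_long, tt_long, "contracting"),
    junction_kinetics(5 - 0.5 * tt_short, tt_short, "contracting")
  )
  avg <- average_kinetics(ks, window_min = 10)
  expect_equal(avg$n_used, 2)
  expect_equal(unique(round(avg$mean_rate, 9)), -0.75)  # mean of -1 and -0.5
  expect_equal(length(avg$mean_rate), 20)               # 10 min at 30 s
})

test_that("junction angles reproduce closed-form cases and invariances", {
  flat <- fit_midline(data.frame(frame = 1, x = c(0, 10, 20), y = c(0, 0, 0)), 1)
  expect_equal(junction_angle(c(0, 0), c(5, 0), flat, 1), 0)
  expect_equal(junction_angle(c(2, 0), c(2, 5), flat, 1), 90)
  diag1 <- fit_midline(data.frame(frame = 1, x = c(0, 10, 20), y = c(0, 10, 20)), 1)
  expect_equal(junction_angle(c(0, 0), c(5, 0), diag1, 1), 45, tolerance = 1e-6)
  # endpoint swap and rigid translation leave the angle unchanged
  curved <- fit_midline(data.frame(frame = 1, x = c(0, 5, 10, 15),
                                   y = c(0, 2, 3, 2.5)), 1)
  a1 <- junction_angle(c(4, 6), c(7, 9), curved, 1)
  a2 <- junction_angle(c(7, 9), c(4, 6), curved, 1)
  expect_equal(a1, a2)
  shift <- c(3, 3)
  curved2 <- fit_midline(data.frame(frame = 1, x = c(0, 5, 10, 15) + shift[1],
                                    y = c(0, 2, 3, 2.5) + shift[2]), 1)
  a3 <- junction_angle(c(4, 6) + shift, c(7, 9) + shift, curved2, 1)
  expect_equal(a1, a3, tolerance = 1e-4)
  expect_true(a1 >= 0 && a1 <= 90)
  # midline coefficients interpolate between anchor frames
  ml <- fit_midline(data.frame(frame = c(1, 1, 1, 11, 11, 11),
                               x = rep(c(0, 10, 20), 2),
                               y = c(0, 0, 0, 10, 10, 10)), 11)
  expect_equal(unname(ml$coef[1, "a0"]), 0, tolerance = 1e-9)
  expect_equal(unname(ml$coef[11, "a0"]), 10, tolerance = 1e-9)
  expect_true(all(diff(ml$coef[, "a0"]) >= 0))  # monotone interpolation
})

test_that("Rayleigh test behaves at its analytic extremes", {
  # all angles equal: p effectively zero
  r1 <- rayleigh_axial_test(rep(30, 20))
  expect_lt(r1$p, 1e-10)
  # exactly antipodal axial pairs after doubling: z = 0, p = 1
  r2 <- rayleigh_axial_test(c(0, 90, 0, 90, 0, 90))
  expect_equal(r2$z, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1)
  # uniform angles: p > 0.05 in >= 95% of seeded replicates
  set.seed(101)
  ps <- replicate(100, rayleigh_axial_test(runif(1000, 0, 180))$p)
  expect_gte(mean(ps > 0.05), 0.95)
  expect_error(rayleigh_axial_test(c(1, 2, 3)), "at least 4")
  # axial duplication doubles the sample
  expect_length(axial_duplicate(c(10, 20)), 4)
})

test_that("rosette sequentiality measures the contraction stagger", {
  # both junctions vanish in the same frame
  sync <- list(list(lengths = c(3, 2, 0), times_min = 0:2),
               list(lengths = c(2, 1, 0), times_min = 0:2))
  s <- rosette_sequentiality(sync)
  expect_equal(s$contract_interval_min, 0)
  expect_equal(s$mode, "synchronous")
  # single junction errors (a T1, not a rosette)
  expect_error(rosette_sequentiality(sync[1]), "at least two")
  # simulator-programmed 3-frame stagger is recovered within one frame
  sim <- get_rosette_sim()
  tr <- sim$truth[1, ]
  pairs <- list(c(15L, 16L), c(15L, 10L))
  traces <- lapply(pairs, function(p) {
    list(lengths = junction_length_series(sim$tissue, p[1], p[2]),
         times_min = sim$times_min <- (seq_len(n_frames(sim$tissue)) - 1) *
           sim$tissue$dt_min)
  })
  sq <- rosette_sequentiality(traces)
  # scripted stagger: 3 frames at 0.5 min; collapse dynamics add ~1 frame
  expect_gte(sq$contract_interval_min, 1)
  expect_lte(sq$contract_interval_min, 2.5)
  expect_equal(sq$mode, "sequential")
})

test_that("rosette hubs are detected and plain rosettes are not", {
  hub_cfg <- sim_config(rows = 6, cols = 6, n_frames = 32, seed = 5,
                        scripted_events = list(
                          script_hub(list(c(15L, 16L), c(15L, 10L)),
                                     onset_frame = 4L)))
  hub_sim <- simulate_tissue(hub_cfg)
  hubs <- detect_rosette_hub(hub_sim$tissue)
  expect_gte(nrow(hubs), 1)
  truth_members <- as.integer(
    strsplit(hub_sim$truth$members[1], "+", fixed = TRUE)[[1]])
  got <- as.integer(strsplit(hubs$members[1], "+", fixed = TRUE)[[1]])
  expect_true(all(got %in% truth_members))
  expect_true(nzchar(hubs$left[1]) && nzchar(hubs$joined[1]))
  # a plain rosette has no membership turnover at its core vertex
  ros <- get_rosette_sim()
  expect_equal(nrow(detect_rosette_hub(ros$tissue)), 0)
})
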