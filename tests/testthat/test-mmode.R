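test_that("M-mode construction satisfies its geometric contracts", {
  sim <- small_sim(n_frames = 20)
  stack <- sim$stack
  center <- c(47, 47)
  mm <- build_mmode(stack, center, "short", 90)
  expect_equal(ncol(mm$matrix), 20)               # one column per frame
  expect_equal(nrow(mm$matrix), length(mm$offsets_px))

  # axis-aligned line through an integer center is an exact column read
  expect_equal(mm$matrix[, 3], stack$frames[, 48, 3])
  mm0 <- build_mmode(stack, center, "long", 0)
  expect_equal(mm0$matrix[, 5], stack$frames[48, , 5])

  expect_error(build_mmode(stack, c(200, 47), "long", 0), "outside")

  # static video: all columns identical
  ps <- beat_params(a_ed = 25, b_ed = 15, a_es = 25, b_es = 15)
  st <- simulate_beating_ventricle(ps, n_frames = 6,
                                   image_shape = c(96, 96))$stack
  mms <- build_mmode(st, c(47.5, 47.5), "short", 90)
  for (j in 2:6) expect_identical(mms$matrix[, j], mms$matrix[, 1])
})

test_that("wall tracing finds symmetric half-maximum edges", {
  sim <- small_sim()
  es <- segment_stack(sim$stack)
  ref <- which.min(es$a_px * es$b_px)
  mm <- build_mmode(sim$stack, c(es$cx[ref], es$cy[ref]), "short", 90)
  tr <- extract_wall_trace(mm)
  expect_false(any(tr$flagged))
  # width oscillates between about 2*b_es and 2*b_ed
  expect_lt(abs(max(tr$width_um) - 2 * 18), 2)
  expect_lt(abs(min(tr$width_um) - 2 * 12.6), 2)
  # edges symmetric about the center (symmetric profile)
  expect_lt(max(abs(tr$edge_low_um + tr$edge_high_um)), 1)
  # per-frame width tracks true 2*b(t)
  expect_lt(max(abs(tr$width_um - 2 * sim$truth$per_frame$b_um)), 2)

  # a line entirely inside the lumen has no usable band on every column
  flat <- mm
  flat$matrix <- matrix(0.9, 11, ncol(mm$matrix))
  flat$offsets_px <- -5:5
  expect_error(extract_wall_trace(flat), "no usable")
})

test_that("dimension extraction averages per-cycle extrema", {
  t_ms <- seq(0, 2990, by = 10)
  tr <- make_wall_trace(t_ms, 60 + 20 * cos(2 * pi * t_ms / 500))
  d <- measure_dimensions(tr, n_cycles = 5)
  expect_equal(d$VDs_um, 40, tolerance = 1e-3)
  expect_equal(d$VDd_um, 80, tolerance = 1e-3)
  expect_equal(d$n_cycles_used, 5)

  # constant width: VDs = VDd
  dc <- measure_dimensions(make_wall_trace(t_ms, rep(55, length(t_ms))))
  expect_equal(dc$VDs_um, dc$VDd_um)

  # fewer cycles than requested: warn, use available
  short <- make_wall_trace(t_ms[t_ms < 1000],
                           60 + 20 * cos(2 * pi * t_ms[t_ms < 1000] / 500))
  expect_warning(ds <- measure_dimensions(short, n_cycles = 5), "available")
  expect_lt(ds$n_cycles_used, 5)
})

test_that("volumes, EF and %FS follow the printed formulas", {
  v <- compute_volumes(short_vds = 42, short_vdd = 60,
                       long_vds = 80, long_vdd = 100)
  expect_equal(v$EDV_pl, 60)            # 4*50*30^2/3 = 60 pl
  expect_equal(v$ESV_pl, 4 * 40 * 21^2 / 3 / 1000)
  expect_equal(v$SV_pl, v$EDV_pl - v$ESV_pl)

  vpi <- compute_volumes(42, 60, 80, 100, include_pi = TRUE)
  expect_equal(vpi$EDV_pl, 60 * pi)

  expect_equal(compute_volumes(0, 60, 80, 100)$ESV_pl, 0)
  expect_warning(compute_volumes(60, 42, 100, 80), "negative")

  ef <- compute_ef_fs(60, 30, short_vds = 36, short_vdd = 60)
  expect_equal(ef$EF, 0.5)
  expect_equal(ef$FS_pct, 40)
  efz <- compute_ef_fs(60, 60, 50, 50)
  expect_equal(efz$EF, 0)
  expect_equal(efz$FS_pct, 0)
  expect_error(compute_ef_fs(0, 0, 36, 60), "positive")
})

test_that("wall velocities are mean slopes between alternating extrema", {
  # triangular ventral wall: 10 um excursion, 100 ms systole, 150 ms diastole
  times <- cumsum(c(0, rep(c(150, 100), 5)))     # i,(o,i)x5 = 11 points
  pos <- rep(c(-20, -30), length.out = 11)       # inward = -20, outward = -30
  pts <- data.frame(time_ms = times, position_um = pos,
                    type = rep(c("inward", "outward"), length.out = 11))
  v <- wall_velocities(pts)
  expect_equal(v$mVWVs_um_ms, 10 / 100)
  expect_equal(v$mVWVd_um_ms, 10 / 150)

  # static wall: zero slopes
  pts0 <- transform(pts, position_um = -25)
  v0 <- wall_velocities(pts0)
  expect_equal(v0$mVWVs_um_ms, 0)
  expect_equal(v0$mVWVd_um_ms, 0)

  bad <- pts; bad$type[2] <- "inward"
  expect_error(wall_velocities(bad), "alternate")
})

test_that("extreme point extraction yields the 11-point scheme", {
  t_ms <- seq(25, 2975, by = 10)   # interior extrema for 6 cycles at 500 ms
  tr <- make_wall_trace(t_ms, 60 + 20 * cos(2 * pi * t_ms / 500))
  pts <- extreme_points(tr, n_cycles = 5)
  expect_equal(nrow(pts), 11)
  expect_equal(sum(pts$type == "inward"), 6)
  expect_equal(sum(pts$type == "outward"), 5)
  expect_equal(pts$type[1], "inward")
  expect_true(all(diff(pts$time_ms) > 0))
  vv <- wall_velocities(pts)
  # symmetric cosine: equal systolic and diastolic mean speeds
  expect_equal(vv$mVWVs_um_ms, vv$mVWVd_um_ms, tolerance = 0.01)
})

test_that("heartbeat counting reports beats over the 15 s window", {
  t_ms <- seq(0, 15000, by = 10)
  y <- cos(2 * pi * t_ms / 500)     # 2 Hz
  hb <- count_heartbeats(y, t_ms, window_s = 15)
  expect_equal(hb$n_beats, 30)
  expect_equal(hb$bpm, 120)
  expect_false(hb$extrapolated)

  t5 <- seq(0, 4999, by = 10)
  hb5 <- count_heartbeats(cos(2 * pi * t5 / 400), t5, window_s = 15)
  expect_equal(hb5$bpm, 150)        # 2.5 Hz, extrapolated from 5 s
  expect_true(hb5$extrapolated)

  expect_warning(h0 <- count_heartbeats(rep(1, 100), t5[1:100]), "0 bpm")
  expect_equal(h0$bpm, 0)
})
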