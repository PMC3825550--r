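test_that("volume series converts ellipse axes through the volume formula", {
  es <- constant_ellipse_series(50, a_px = 50, b_px = 30)
  vs <- volume_series(es, pixel_size = 1)
  expect_true(all(vs$volume_pl == 60))

  es2 <- constant_ellipse_series(50, a_px = 25, b_px = 15)
  vs2 <- volume_series(es2, pixel_size = 2)    # same axes in um
  expect_true(all(vs2$volume_pl == 60))

  bad <- es; bad$b_px[3] <- 0
  expect_error(volume_series(bad, 1), "non-positive")
})

test_that("fundamental period is found from the dominant spectral peak", {
  t_ms <- 1000 * (0:99) / 20                    # 20 fps, 5 s
  vs <- make_volume_series(t_ms, 50 + 10 * cos(2 * pi * t_ms / 400))
  expect_lt(abs(estimate_fundamental(vs) - 400), 5)

  # two cycles exactly spanning the record
  t2 <- 1000 * (0:79) / 20
  vs2 <- make_volume_series(t2, 50 + 10 * sin(2 * pi * 2 * t2 / 4000))
  expect_equal(estimate_fundamental(vs2), 2000, tolerance = 1e-6)

  expect_error(estimate_fundamental(make_volume_series(t_ms, rep(5, 100))),
               "flat")
})

test_that("Fourier fitting is exact on signals inside the model class", {
  t_ms <- 1000 * (0:99) / 20
  # constant series
  f0 <- fourier_fit(make_volume_series(t_ms, rep(42, 100)), period_ms = 500)
  expect_equal(f0$a0, 42, tolerance = 1e-9)
  expect_lt(max(abs(c(f0$a, f0$b))), 1e-9)

  # single harmonic
  f1 <- fourier_fit(make_volume_series(t_ms, 50 + 10 * cos(2 * pi * t_ms / 400)),
                    period_ms = 400)
  expect_equal(f1$a[1], 10, tolerance = 1e-6)
  expect_lt(max(abs(c(f1$a[-1], f1$b))), 1e-6)
  expect_lt(f1$rms_residual, 1e-9)

  expect_error(fourier_fit(make_volume_series(t_ms[1:8], rep(1, 8)), 400),
               "at least")
})

test_that("analytic derivative matches finite differences", {
  t_ms <- 1000 * (0:99) / 20
  set.seed(5)
  a <- runif(5, -3, 3); b <- runif(5, -3, 3)
  w <- 2 * pi * outer(t_ms, 1:5) / 500
  v <- 60 + drop(cos(w) %*% a + sin(w) %*% b)
  fit <- fourier_fit(make_volume_series(t_ms, v), period_ms = 500)
  tg <- seq(0, 500, length.out = 2001)
  h <- 1e-3
  fd <- (fourier_eval(fit, tg + h) - fourier_eval(fit, tg - h)) / (2 * h)
  an <- fourier_deriv(fit, tg)
  expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-6)
})

test_that("TVC parameters of a single-harmonic curve match analytic values", {
  t_ms <- 1000 * (0:99) / 20
  vs <- make_volume_series(t_ms, 50 + 10 * cos(2 * pi * t_ms / 400))
  fit <- fourier_fit(vs, period_ms = 400)
  m <- tvc_parameters(fit)
  expect_equal(m$V1, 60, tolerance = 1e-4)
  expect_equal(m$V2, 40, tolerance = 1e-4)
  expect_equal(m$EF_pct, 100 * 20 / 60, tolerance = 1e-3)
  expect_equal(m$V3, 55, tolerance = 1e-3)          # v(T/6)
  expect_equal(m$oneThirdEF_pct, 100 * 5 / 60, tolerance = 1e-2)
  expect_equal(m$V4, 45, tolerance = 1e-3)          # v(T/2 + T/6)
  expect_equal(m$oneThirdFF_pct, 25, tolerance = 1e-2)
  expect_equal(m$D1, -10 * 2 * pi / 400, tolerance = 1e-6)
  expect_equal(m$D2, 10 * 2 * pi / 400, tolerance = 1e-6)
  expect_equal(m$TPE_ms, 100, tolerance = 0.2)
  expect_equal(m$TPF_ms, 100, tolerance = 0.2)
  expect_equal(m$PER, -m$D1 * 1000 / 60, tolerance = 1e-6)
  expect_equal(m$PFR, m$D2 * 1000 / 60, tolerance = 1e-6)
  # symmetric waveform: TD1 = TD2, -D1 = D2
  expect_equal(m$TD1, m$TD2, tolerance = 0.2)
  expect_equal(-m$D1, m$D2, tolerance = 1e-6)
  # literal normalization option for 1/3FR
  ml <- tvc_parameters(fit, literal_one_third_fr = TRUE)
  expect_equal(ml$oneThirdFR, m$oneThirdFR / 400, tolerance = 1e-9)

  # zero amplitude: no extrema
  flatfit <- fourier_fit(make_volume_series(t_ms, rep(50, 100)),
                         period_ms = 400)
  expect_error(tvc_parameters(flatfit), "extrema")
})

test_that("TVC EF agrees with M-mode EF on the same simulation", {
  # 600 ms cycle so all five harmonics are below the 20 fps Nyquist limit
  sim <- small_sim(period_ms = 600, n_frames = 62)
  es <- segment_stack(sim$stack)
  mm <- suppressWarnings(analyze_mmode(sim$stack, ellipses = es))
  tv <- analyze_tvc(es, pixel_size = 1)
  expect_lt(abs(tv$EF_pct - mm$EF_pct), 5)
  # peak rates within 10% of the analytic waveform truth
  expect_lt(abs(tv$D1 - sim$truth$peak_ejection_rate_pl_ms) /
              abs(sim$truth$peak_ejection_rate_pl_ms), 0.1)
  expect_lt(abs(tv$D2 - sim$truth$peak_filling_rate_pl_ms) /
              sim$truth$peak_filling_rate_pl_ms, 0.1)
})
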