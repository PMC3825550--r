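#' Per-frame ventricular volume series
#'
#' Converts a per-frame ellipse series (from [segment_stack()] or
#' [ellipses_from_contours()]) into a time-volume curve: for each frame,
#' the long and short semi-axes in um feed the configured prolate-spheroid
#' volume formula (see [volume_from_axes()]).
#'
#' @param ellipses an `ellipse_series` data frame.
#' @param pixel_size microns per pixel.
#' @param include_pi volume formula flag.
#' @return A `volume_series` data frame: `t_ms`, `volume_pl`.
#' @export
volume_series <- function(ellipses, pixel_size, include_pi = FALSE) {
  if (!all(c("t_ms", "a_px", "b_px") %in% names(ellipses)))
    stop_input("`ellipses` must have t_ms, a_px, b_px columns")
  check_positive_scalar(pixel_size, "pixel_size")
  if (any(!is.finite(ellipses$a_px)) || any(!is.finite(ellipses$b_px)))
    stop_input("missing ellipse axes: interpolate failed frames first")
  if (any(ellipses$a_px <= 0 | ellipses$b_px <= 0))
    stop_input("non-positive ellipse axes (zero-area frame)")
  out <- data.frame(
    t_ms = ellipses$t_ms,
    volume_pl = volume_from_axes(ellipses$a_px * pixel_size,
                                 ellipses$b_px * pixel_size, include_pi))
  class(out) <- c("volume_series", "data.frame")
  out
}

#' Estimate the fundamental cardiac period of a volume series
#'
#' Locates the dominant nonzero-frequency peak of the discrete Fourier
#' spectrum of the mean-subtracted series and refines it by local
#' quadratic interpolation of the spectral magnitude.
#'
#' @param vs a `volume_series` (or any data frame with `t_ms` and
#'   `volume_pl`), uniformly sampled, spanning at least two cycles.
#' @return Estimated period in ms.
#' @export
estimate_fundamental <- function(vs) {
  v <- vs$volume_pl; t_ms <- vs$t_ms
  n <- length(v)
  if (n < 4L) stop_input("too few samples to estimate a period")
  dt <- diff(t_ms)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop_input("period estimation requires uniform sampling")
  x <- v - mean(v)
  if (max(abs(x)) == 0) stop_input("flat volume series: no fundamental")
  mag <- Mod(fft(x))
  ks <- 2:(floor(n / 2) + 1L)             # nonzero frequencies
  k <- ks[which.max(mag[ks])]
  y1 <- if (k - 1L >= 1L) mag[k - 1L] else 0
  y2 <- mag[k]; y3 <- if (k + 1L <= n) mag[k + 1L] else 0
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else max(-0.5, min(0.5, 0.5 * (y1 - y3) / denom))
  freq_bins <- (k - 1L) + delta           # cycles per record
  n * dt[1L] / freq_bins
}

#' Fit a truncated Fourier series to a volume series
#'
#' Least-squares fit of
#' `a0 + sum_k (a_k cos(2 pi k t / T) + b_k sin(2 pi k t / T))`
#' with `K` harmonics (five by default) at fundamental period `T`.
#'
#' @param vs a `volume_series`.
#' @param period_ms fundamental period; estimated with
#'   [estimate_fundamental()] when `NULL`.
#' @param k number of harmonics.
#' @return A `fourier_fit`: `a0`, `a`, `b` (length-`k` coefficient
#'   vectors), `period_ms`, `k`, `rms_residual`.
#' @export
fourier_fit <- function(vs, period_ms = NULL, k = 5) {
  v <- vs$volume_pl; t_ms <- vs$t_ms
  n <- length(v)
  if (n < 2 * k + 1)
    stop_input(sprintf("need at least %d samples for %d harmonics",
                       2 * k + 1, k))
  if (is.null(period_ms)) period_ms <- estimate_fundamental(vs)
  check_positive_scalar(period_ms, "period_ms")
  w <- 2 * pi * outer(t_ms, seq_len(k)) / period_ms
  X <- cbind(1, cos(w), sin(w))
  # Harmonics above the Nyquist frequency of uniform sampling alias exactly
  # onto lower ones (and the sine term vanishes at Nyquist itself); their
  # columns are excluded and the coefficients reported as zero.
  keep <- rep(TRUE, 2L * k + 1L)
  dt <- diff(t_ms)
  if (max(abs(dt - dt[1L])) < 1e-9 * dt[1L]) {
    fk <- seq_len(k) / period_ms
    nyq <- 1 / (2 * dt[1L])
    keep[1L + seq_len(k)] <- fk < nyq + 1e-12            # cosines
    keep[1L + k + seq_len(k)] <- fk < nyq - 1e-12        # sines
  }
  fit <- lm.fit(X[, keep, drop = FALSE], v)
  cf <- rep(0, 2L * k + 1L)
  cf[keep] <- fit$coefficients
  cf[is.na(cf)] <- 0
  structure(list(a0 = cf[[1L]], a = unname(cf[2:(k + 1L)]),
                 b = unname(cf[(k + 2L):(2L * k + 1L)]),
                 period_ms = period_ms, k = k,
                 rms_residual = sqrt(mean(fit$residuals^2))),
            class = "fourier_fit")
}

#' Evaluate a fitted Fourier series
#' @param fit a `fourier_fit`.
#' @param t_ms times (ms).
#' @return Fitted values at `t_ms`.
#' @export
fourier_eval <- function(fit, t_ms) {
  w <- 2 * pi * outer(t_ms, seq_len(fit$k)) / fit$period_ms
  drop(fit$a0 + cos(w) %*% fit$a + sin(w) %*% fit$b)
}

#' Analytic derivative of a fitted Fourier series
#' @param fit a `fourier_fit`.
#' @param t_ms times (ms).
#' @return Term-wise analytic derivative dV/dt at `t_ms` (pl/ms).
#' @export
fourier_deriv <- function(fit, t_ms) {
  kk <- seq_len(fit$k)
  om <- 2 * pi * kk / fit$period_ms
  w <- outer(t_ms, om)
  drop(-sin(w) %*% (fit$a * om) + cos(w) %*% (fit$b * om))
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("fourier_fit: %d harmonics, T = %.1f ms, a0 = %.2f pl, RMS residual %.3g\n",
              x$k, x$period_ms, x$a0, x$rms_residual))
  invisible(x)
}

#' Ejection and filling parameters of a fitted time-volume curve
#'
#' Evaluates the fitted curve and its analytic derivative on a dense grid
#' over one period (resolution `T / grid_n` with local quadratic
#' refinement of every extremum) and derives the standard
#' ventriculography parameter set. End-diastole `t_ED` is the (earliest)
#' global maximum of the fitted curve with volume `V1`; end-systole
#' `t_ES` the following minimum with volume `V2`. Ejection spans
#' `[t_ED, t_ES]` and filling the remainder of the cycle. `V3` and `V4`
#' are the volumes one third into ejection and filling; `D1`/`D2` the
#' extreme (peak) derivatives during ejection/filling, reached `TD1`/
#' `TD2` ms after the start of their phase; `D3`/`D4` the mean
#' derivatives over the first third of each phase. Derived indices:
#'
#' * `EF_pct = 100 (V1 - V2) / V1`
#' * `oneThirdEF_pct = 100 (V1 - V3) / V1`
#' * `oneThirdFF_pct = 100 (V4 - V2) / (V1 - V2)`
#' * `TPE = TD1`, `TPF = TD2` (ms)
#' * `oneThirdER = -D3 x 1000 / V1`, `PER = -D1 x 1000 / V1`
#' * `oneThirdFR = D4 x 1000 / V1` (or `D4 x 1000 / (T V1)` with
#'   `literal_one_third_fr = TRUE`), `PFR = D2 x 1000 / V1`
#'
#' The raw phase volumes `V1..V4` (pl) and rates `D1..D4` (pl/ms) are
#' returned alongside the EDV-normalized indices.
#'
#' @param fit a `fourier_fit`.
#' @param grid_n dense-grid resolution (samples per period).
#' @param literal_one_third_fr use the alternative `1/(T V1)`
#'   normalization for the first-third filling rate.
#' @return A `tvc_metrics` list (see Details).
#' @export
tvc_parameters <- function(fit, grid_n = 2048, literal_one_third_fr = FALSE) {
  stopifnot(inherits(fit, "fourier_fit"))
  T <- fit$period_ms
  h <- T / grid_n
  tg <- (0:(grid_n - 1L)) * h
  v <- fourier_eval(fit, tg)
  if (diff(range(v)) <= 1e-9 * max(abs(v), 1e-12))
    stop_input("fitted curve has no distinct extrema")

  wrap <- function(i) ((i - 1L) %% grid_n) + 1L
  refine_circ <- function(i, sgn) {
    y1 <- sgn * v[wrap(i - 1L)]; y2 <- sgn * v[wrap(i)]
    y3 <- sgn * v[wrap(i + 1L)]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom == 0) 0 else max(-0.5, min(0.5, 0.5 * (y1 - y3) / denom))
    tt <- (i - 1L + delta) * h
    c(tt, sgn * (y2 - 0.25 * (y1 - y3) * delta))
  }
  i_ed <- which.max(v)                        # earliest tie by which.max
  ed <- refine_circ(i_ed, 1)
  t_ed <- ed[1L]; V1 <- ed[2L]
  # following minimum, scanning forward circularly from i_ed
  ahead <- wrap(i_ed + seq_len(grid_n - 1L))
  i_es <- ahead[which.min(v[ahead])]
  es <- refine_circ(i_es, -1)
  t_es_raw <- es[1L]; V2 <- es[2L]
  t_es <- if (t_es_raw > t_ed) t_es_raw else t_es_raw + T
  T_ej <- t_es - t_ed
  T_fill <- T - T_ej
  if (T_ej <= 0 || T_fill <= 0)
    stop_input("degenerate ejection/filling phases")

  V3 <- fourier_eval(fit, t_ed + T_ej / 3)
  V4 <- fourier_eval(fit, t_es + T_fill / 3)

  phase_extreme <- function(t0, t1, sgn) {     # sgn=-1: min, +1: max of v'
    ts <- seq(t0, t1, length.out = grid_n %/% 2)
    dv <- fourier_deriv(fit, ts)
    i <- which.max(sgn * dv)
    r <- refine_quadratic(ts[1L], ts[2L] - ts[1L], sgn * dv, i)
    c(r[1L], sgn * r[2L])
  }
  pe <- phase_extreme(t_ed, t_es, -1)
  D1 <- pe[2L]; TD1 <- pe[1L] - t_ed
  pf <- phase_extreme(t_es, t_ed + T, 1)
  D2 <- pf[2L]; TD2 <- pf[1L] - t_es
  D3 <- (V3 - V1) / (T_ej / 3)
  D4 <- (V4 - V2) / (T_fill / 3)

  one_third_fr <- if (literal_one_third_fr) D4 * 1000 / (T * V1)
                  else D4 * 1000 / V1
  structure(list(
    V1 = V1, V2 = V2, V3 = V3, V4 = V4,
    D1 = D1, D2 = D2, D3 = D3, D4 = D4,
    TD1 = TD1, TD2 = TD2,
    EDV_pl = V1, ESV_pl = V2, SV_pl = V1 - V2,
    EF_pct = 100 * (V1 - V2) / V1,
    oneThirdEF_pct = 100 * (V1 - V3) / V1,
    oneThirdFF_pct = 100 * (V4 - V2) / (V1 - V2),
    TPE_ms = TD1, TPF_ms = TD2,
    oneThirdER = -D3 * 1000 / V1,
    PER = -D1 * 1000 / V1,
    oneThirdFR = one_third_fr,
    PFR = D2 * 1000 / V1,
    period_ms = T, t_ED_ms = t_ed, t_ES_ms = t_es,
    ejection_ms = T_ej, filling_ms = T_fill,
    literal_one_third_fr = literal_one_third_fr),
    class = "tvc_metrics")
}

#' @export
print.tvc_metrics <- function(x, ...) {
  cat("Time-volume curve metrics\n")
  cat(sprintf("  EDV %.2f, ESV %.2f pl;  EF %.1f%%, 1/3EF %.1f%%, 1/3FF %.1f%%\n",
              x$V1, x$V2, x$EF_pct, x$oneThirdEF_pct, x$oneThirdFF_pct))
  cat(sprintf("  TPE %.0f ms, TPF %.0f ms;  D1 %.4f, D2 %.4f pl/ms\n",
              x$TPE_ms, x$TPF_ms, x$D1, x$D2))
  cat(sprintf("  PER %.3f, 1/3ER %.3f, PFR %.3f, 1/3FR %.3f (x1000/EDV)\n",
              x$PER, x$oneThirdER, x$PFR, x$oneThirdFR))
  invisible(x)
}

#' Full time-volume-curve analysis from an ellipse series
#'
#' Convenience wrapper: [volume_series()], [fourier_fit()] (five
#' harmonics by default) and [tvc_parameters()].
#'
#' @param ellipses an `ellipse_series`.
#' @param pixel_size microns per pixel.
#' @param period_ms fundamental period (estimated when `NULL`).
#' @param harmonics number of Fourier harmonics.
#' @param include_pi volume formula flag.
#' @param ... passed to [tvc_parameters()].
#' @return A `tvc_metrics` list with the `fourier_fit` attached as
#'   element `fit` and the series as `series`.
#' @export
analyze_tvc <- function(ellipses, pixel_size, period_ms = NULL,
                        harmonics = 5, include_pi = FALSE, ...) {
  vs <- volume_series(ellipses, pixel_size, include_pi)
  fit <- fourier_fit(vs, period_ms, harmonics)
  out <- tvc_parameters(fit, ...)
  out$fit <- fit
  out$series <- vs
  out
}
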