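#' Build an M-mode pseudo-linescan image
#'
#' Samples every frame along a fixed single-pixel-wide line through a given
#' anchor point (normally the center of mass of the reference end-systolic
#' lumen), producing a position x time image in which wall motion appears
#' as bright/dark traces. Sampling is bilinear; for axis-aligned lines
#' through an integer center this reduces to an exact row/column
#' extraction.
#'
#' @param stack a [frame_stack()].
#' @param center anchor point `c(x, y)` in 0-based pixel coordinates; must
#'   lie inside the frame.
#' @param axis label for the line, `"long"` or `"short"` (metadata only;
#'   the geometry is set by `line_angle_deg`).
#' @param line_angle_deg angle of the line in degrees from the image x
#'   axis (y pointing down); 0 samples a row, 90 a column.
#' @return An `mmode_image`: `matrix` (position x time), `offsets_px`
#'   (signed position of each row along the line, 0 at `center`), `axis`,
#'   `line_angle_deg`, `center`, `pixel_size`, `fps`, `times_ms`.
#' @export
build_mmode <- function(stack, center, axis = c("long", "short"),
                        line_angle_deg = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  axis <- match.arg(axis)
  d <- dim(stack$frames); rows <- d[1L]; cols <- d[2L]
  cx <- center[[1L]]; cy <- center[[2L]]
  if (cx < 0 || cx > cols - 1 || cy < 0 || cy > rows - 1)
    stop_input("center lies outside the frame")
  th <- line_angle_deg * pi / 180
  dx <- cos(th); dy <- sin(th)
  # clip the line to the frame bounds
  lim <- function(c0, d0, hi) {
    if (abs(d0) < 1e-12) return(c(-Inf, Inf))
    sort(c((0 - c0) / d0, (hi - c0) / d0))
  }
  lx <- lim(cx, dx, cols - 1); ly <- lim(cy, dy, rows - 1)
  p_min <- max(lx[1L], ly[1L]); p_max <- min(lx[2L], ly[2L])
  offsets <- seq(ceiling(p_min - 1e-9), floor(p_max + 1e-9))
  px <- cx + offsets * dx
  py <- cy + offsets * dy
  # bilinear weights, shared across frames
  x0 <- pmin(pmax(floor(px), 0), cols - 2); fx <- px - x0
  y0 <- pmin(pmax(floor(py), 0), rows - 2); fy <- py - y0
  i0 <- y0 + 1L; j0 <- x0 + 1L
  n <- n_frames(stack)
  m <- matrix(0, nrow = length(offsets), ncol = n)
  for (t in seq_len(n)) {
    fr <- stack$frames[, , t]
    m[, t] <-
      fr[cbind(i0,      j0)]      * (1 - fx) * (1 - fy) +
      fr[cbind(i0,      j0 + 1L)] * fx       * (1 - fy) +
      fr[cbind(i0 + 1L, j0)]      * (1 - fx) * fy +
      fr[cbind(i0 + 1L, j0 + 1L)] * fx       * fy
  }
  structure(list(matrix = m, offsets_px = offsets, axis = axis,
                 line_angle_deg = line_angle_deg, center = c(x = cx, y = cy),
                 pixel_size = stack$pixel_size, fps = stack$fps,
                 times_ms = stack$times_ms),
            class = "mmode_image")
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf("mmode_image (%s axis, %.1f deg): %d px x %d frames\n",
              x$axis, x$line_angle_deg, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Trace the inner ventricular wall on an M-mode image
#'
#' For each column (frame), the profile is Gaussian-smoothed and the two
#' lumen-wall transitions nearest the line center are located as sub-pixel
#' half-maximum crossings: walking outward from the center, the first
#' position on each side where the profile falls below the midpoint of its
#' minimum and maximum. Columns with no usable bright band (no contrast,
#' or center outside the lumen) are flagged and linearly interpolated when
#' no more than `max_fail_frac` of columns fail.
#'
#' @param m an `mmode_image`.
#' @param smooth_sigma_px Gaussian smoothing sd along the line, in px.
#' @param flat_tol minimum profile contrast, as a fraction of the profile
#'   maximum, below which a column is flagged.
#' @param max_fail_frac maximum tolerated fraction of flagged columns.
#' @return A `wall_trace` data frame: `frame`, `t_ms`, `edge_low_um`,
#'   `edge_high_um` (signed positions of the two inner-wall edges along
#'   the line, um), `width_um` (lumen width), `flagged`.
#' @export
extract_wall_trace <- function(m, smooth_sigma_px = 1, flat_tol = 0.2,
                               max_fail_frac = 0.1) {
  stopifnot(inherits(m, "mmode_image"))
  n <- ncol(m$matrix)
  i_center <- which.min(abs(m$offsets_px))
  lo <- hi <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (j in seq_len(n)) {
    sm <- gauss_smooth(m$matrix[, j], smooth_sigma_px)
    rng <- range(sm)
    if (diff(rng) < flat_tol * max(rng[2L], 1e-12)) {
      flagged[j] <- TRUE; next
    }
    half <- mean(rng)
    if (sm[i_center] < half) { flagged[j] <- TRUE; next }
    cross_out <- function(dir) {
      k <- i_center
      while (k + dir >= 1L && k + dir <= length(sm) && sm[k + dir] >= half)
        k <- k + dir
      if (k + dir < 1L || k + dir > length(sm)) return(NA_real_)
      frac <- (sm[k] - half) / (sm[k] - sm[k + dir])
      m$offsets_px[k] + dir * frac
    }
    p_lo <- cross_out(-1L); p_hi <- cross_out(1L)
    if (is.na(p_lo) || is.na(p_hi)) { flagged[j] <- TRUE; next }
    lo[j] <- p_lo; hi[j] <- p_hi
  }
  nfail <- sum(flagged)
  if (nfail > 0) {
    if (nfail >= n || nfail > max_fail_frac * n)
      stop_input(sprintf("no usable bright band in %d/%d columns", nfail, n))
    ok <- !flagged
    lo[!ok] <- stats::approx(which(ok), lo[ok], xout = which(!ok), rule = 2)$y
    hi[!ok] <- stats::approx(which(ok), hi[ok], xout = which(!ok), rule = 2)$y
  }
  out <- data.frame(frame = seq_len(n), t_ms = m$times_ms,
                    edge_low_um = lo * m$pixel_size,
                    edge_high_um = hi * m$pixel_size,
                    width_um = (hi - lo) * m$pixel_size,
                    flagged = flagged)
  attr(out, "axis") <- m$axis
  class(out) <- c("wall_trace", "data.frame")
  out
}

#' End-systolic and end-diastolic dimensions from a wall trace
#'
#' Per-cycle extrema of the lumen width are located by prominence-filtered
#' peak detection with three-point quadratic refinement; the end-systolic
#' dimension VDs is the mean of the first `n_cycles` per-cycle minima and
#' the end-diastolic dimension VDd the mean of the first `n_cycles`
#' maxima. Five cycles are analyzed by default.
#'
#' @param trace a `wall_trace`.
#' @param n_cycles number of diastoles/systoles to average.
#' @param min_prom_frac peak prominence threshold, as a fraction of the
#'   width range.
#' @return A list: `VDs_um`, `VDd_um`, `n_cycles_used`, plus `systolic`
#'   and `diastolic` data frames of per-cycle extremum times and widths.
#' @export
measure_dimensions <- function(trace, n_cycles = 5, min_prom_frac = 0.5) {
  stopifnot(inherits(trace, "wall_trace"))
  w <- trace$width_um; t_ms <- trace$t_ms
  rng <- diff(range(w))
  if (rng == 0)
    return(list(VDs_um = w[1L], VDd_um = w[1L], n_cycles_used = 0L,
                systolic = NULL, diastolic = NULL))
  prom <- min_prom_frac * rng
  i_max <- find_peaks(w, prom)
  i_min <- find_peaks(-w, prom)
  refine <- function(idx, sgn) {
    t(vapply(idx, function(i)
      refine_quadratic(t_ms[1L], t_ms[2L] - t_ms[1L], sgn * w, i) *
        c(1, sgn), numeric(2)))
  }
  dia <- refine(i_max, 1)
  sys <- refine(i_min, -1)
  avail <- min(nrow(dia), nrow(sys))
  if (avail < 1L) stop_input("no complete cardiac cycle in the trace")
  used <- min(n_cycles, avail)
  if (used < n_cycles)
    warning(sprintf("only %d cycles available (requested %d)", avail,
                    n_cycles), call. = FALSE)
  list(VDs_um = mean(sys[seq_len(used), 2L]),
       VDd_um = mean(dia[seq_len(used), 2L]),
       n_cycles_used = used,
       systolic = data.frame(t_ms = sys[, 1L], width_um = sys[, 2L]),
       diastolic = data.frame(t_ms = dia[, 1L], width_um = dia[, 2L]))
}

#' Ventricular volumes from M-mode dimensions
#'
#' End-diastolic and end-systolic volumes from the long and short internal
#' dimensions under the prolate-spheroid model `4 a b^2 / 3` with
#' `a = long dimension / 2`, `b = short dimension / 2` (see
#' [volume_from_axes()]); the stroke volume is their difference.
#'
#' @param short_vds,short_vdd,long_vds,long_vdd dimensions in um.
#' @param include_pi include the factor pi in the volume formula.
#' @return A list: `EDV_pl`, `ESV_pl`, `SV_pl`.
#' @export
compute_volumes <- function(short_vds, short_vdd, long_vds, long_vdd,
                            include_pi = FALSE) {
  edv <- volume_from_axes(long_vdd / 2, short_vdd / 2, include_pi)
  esv <- volume_from_axes(long_vds / 2, short_vds / 2, include_pi)
  sv <- edv - esv
  if (sv < 0)
    warning("negative stroke volume (ESV > EDV): physiologically inverted",
            call. = FALSE)
  list(EDV_pl = edv, ESV_pl = esv, SV_pl = sv)
}

#' Ejection fraction and fractional shortening
#'
#' `EF = (EDV - ESV) / EDV` and
#' `%FS = 100 (short VDd - short VDs) / short VDd`.
#'
#' @param edv,esv volumes (pl), `edv > 0`.
#' @param short_vds,short_vdd short-axis dimensions (um), `short_vdd > 0`.
#' @return A list: `EF` (fraction), `EF_pct`, `FS_pct`.
#' @export
compute_ef_fs <- function(edv, esv, short_vds, short_vdd) {
  if (edv <= 0) stop_input("EDV must be positive")
  if (short_vdd <= 0) stop_input("short VDd must be positive")
  ef <- (edv - esv) / edv
  list(EF = ef, EF_pct = 100 * ef,
       FS_pct = 100 * (short_vdd - short_vds) / short_vdd)
}

#' Alternating wall-excursion extrema from a wall trace
#'
#' Locates the maximal inward (systolic) and outward (diastolic)
#' excursions of one inner-wall edge (the ventral/low edge by default) as
#' alternating extrema, quadratic-refined in time and position. The
#' default of `n_cycles = 5` yields the classic 11-point scheme: 6 inward
#' and 5 outward points.
#'
#' @param trace a `wall_trace`.
#' @param n_cycles number of cycles; `n_cycles + 1` inward and `n_cycles`
#'   outward points are returned when available.
#' @param wall `"low"` (ventral under the standard mounting) or `"high"`.
#' @param min_prom_frac peak prominence threshold, fraction of the edge
#'   excursion range.
#' @return An `extreme_points` data frame: `time_ms`, `position_um`,
#'   `type` (`"inward"`/`"outward"`), alternating, starting and ending
#'   inward when the trace allows.
#' @export
extreme_points <- function(trace, n_cycles = 5, wall = c("low", "high"),
                           min_prom_frac = 0.5) {
  stopifnot(inherits(trace, "wall_trace"))
  wall <- match.arg(wall)
  e <- if (wall == "low") trace$edge_low_um else -trace$edge_high_um
  # for the low edge, inward motion = position increases toward the center
  t_ms <- trace$t_ms
  rng <- diff(range(e))
  if (rng == 0) stop_input("static wall: no excursions to locate")
  prom <- min_prom_frac * rng
  refine_at <- function(idx, sgn) {
    t(vapply(idx, function(i)
      refine_quadratic(t_ms[1L], t_ms[2L] - t_ms[1L], sgn * e, i) *
        c(1, sgn), numeric(2)))
  }
  inw <- refine_at(find_peaks(e, prom), 1)      # maxima of low edge
  outw <- refine_at(find_peaks(-e, prom), -1)   # minima
  if (!nrow(inw) || !nrow(outw))
    stop_input("could not locate both inward and outward excursions")
  pts <- rbind(data.frame(time_ms = inw[, 1L],
                          position_um = if (wall == "low") inw[, 2L]
                                        else -inw[, 2L], type = "inward"),
               data.frame(time_ms = outw[, 1L],
                          position_um = if (wall == "low") outw[, 2L]
                                        else -outw[, 2L], type = "outward"))
  pts <- pts[order(pts$time_ms), ]
  # enforce alternation: of consecutive same-type points keep the first
  keep <- c(TRUE, pts$type[-1L] != pts$type[-nrow(pts)])
  pts <- pts[keep, ]
  # window of n+1 inward / n outward starting at the first inward point
  first_in <- match("inward", pts$type)
  pts <- pts[first_in:nrow(pts), ]
  want <- 2L * n_cycles + 1L
  if (nrow(pts) > want) pts <- pts[seq_len(want), ]
  if (pts$type[nrow(pts)] == "outward") pts <- pts[-nrow(pts), ]
  if (nrow(pts) < want)
    warning(sprintf("only %d alternating extrema available (wanted %d)",
                    nrow(pts), want), call. = FALSE)
  rownames(pts) <- NULL
  class(pts) <- c("extreme_points", "data.frame")
  pts
}

#' Mean ventricular wall velocities during systole and diastole
#'
#' From an alternating set of maximal inward/outward wall excursions, each
#' systolic slope is `|delta position / delta time|` between a consecutive
#' outward-inward point pair (contraction) and each diastolic slope
#' between an inward-outward pair (relaxation); mVWVs and mVWVd are the
#' means of the available slopes (five each under the default 11-point
#' scheme).
#'
#' @param pts an `extreme_points` data frame (or any data frame with
#'   `time_ms`, `position_um`, `type` columns, alternating in time).
#' @return A list: `mVWVs_um_ms`, `mVWVd_um_ms`.
#' @export
wall_velocities <- function(pts) {
  if (!all(c("time_ms", "position_um", "type") %in% names(pts)))
    stop_input("`pts` must have time_ms, position_um, type columns")
  if (is.unsorted(pts$time_ms, strictly = TRUE))
    stop_input("extreme point times must be strictly increasing")
  ty <- as.character(pts$type)
  if (any(ty[-1L] == ty[-length(ty)]))
    stop_input("extreme point types must alternate")
  n <- nrow(pts)
  if (n < 2L) stop_input("need at least two extreme points")
  slope <- abs(diff(pts$position_um) / diff(pts$time_ms))
  sys <- slope[ty[-n] == "outward"]   # outward -> inward: contraction
  dia <- slope[ty[-n] == "inward"]    # inward -> outward: relaxation
  list(mVWVs_um_ms = if (length(sys)) mean(sys) else 0,
       mVWVd_um_ms = if (length(dia)) mean(dia) else 0)
}

#' Heart rate by counting beats over a 15-second window
#'
#' Detects cycle maxima of a lumen-width trace (or any periodic series) by
#' prominence-filtered peak detection, takes the cycle length as the
#' median inter-peak interval, and reports the number of beats in the
#' counting window (15 s by default) with the corresponding rate in bpm.
#' When the recording is shorter than the window the count is
#' extrapolated from the observed cycle length and flagged.
#'
#' @param x a `wall_trace`, or a numeric series (then supply `times_ms`).
#' @param times_ms per-sample times in ms (ignored for a `wall_trace`).
#' @param window_s counting window in seconds.
#' @param min_prom_frac peak prominence threshold, fraction of the signal
#'   range.
#' @return A list: `bpm`, `n_beats` (beats in the window), `period_ms`,
#'   `extrapolated`.
#' @export
count_heartbeats <- function(x, times_ms = NULL, window_s = 15,
                             min_prom_frac = 0.5) {
  if (inherits(x, "wall_trace")) {
    y <- x$width_um; times_ms <- x$t_ms
  } else {
    y <- as.numeric(x)
    if (is.null(times_ms)) stop_input("`times_ms` required for a raw series")
  }
  dur_ms <- times_ms[length(times_ms)] - times_ms[1L]
  if (dur_ms <= 0) stop_input("trace duration must be positive")
  ys <- gauss_smooth(y, 1)
  rng <- diff(range(ys))
  peaks <- if (rng > 0) find_peaks(ys, min_prom_frac * rng) else integer(0)
  if (length(peaks) < 2L) {
    warning("fewer than two cycle maxima detected: reporting 0 bpm",
            call. = FALSE)
    return(list(bpm = 0, n_beats = 0L, period_ms = NA_real_,
                extrapolated = dur_ms < 1000 * window_s))
  }
  dt <- stats::median(diff(times_ms))
  peak_t <- vapply(peaks, function(i)
    refine_quadratic(times_ms[1L], dt, ys, i)[1L], numeric(1))
  period_ms <- mean(diff(peak_t))
  n_beats <- round(1000 * window_s / period_ms)
  extrapolated <- dur_ms < 1000 * window_s
  # within a full window report the integer count; for shorter records the
  # rate extrapolated from the observed cycle length
  bpm <- if (extrapolated) 60000 / period_ms else n_beats * 60 / window_s
  list(bpm = bpm, n_beats = n_beats,
       period_ms = period_ms, extrapolated = extrapolated)
}

#' Full M-mode analysis of a ventricle recording
#'
#' End-to-end workflow: per-frame segmentation (unless an ellipse series
#' is supplied), choice of the reference end-systolic frame (smallest
#' fitted lumen), placement of the long- and short-axis lines through its
#' center of mass, M-mode construction, wall tracing, dimension
#' extraction over `n_cycles` cycles, prolate-spheroid volumes, EF, %FS,
#' wall velocities and heart rate.
#'
#' @param stack a [frame_stack()].
#' @param ellipses optional precomputed `ellipse_series` (from
#'   [segment_stack()] or [ellipses_from_contours()]).
#' @param axes `"principal"` aligns the lines with the principal axes of
#'   the reference end-systolic ellipse; `"image"` uses strict
#'   horizontal/vertical lines (the standard mounting).
#' @param n_cycles diastoles/systoles to average.
#' @param include_pi volume formula flag.
#' @param window_s heartbeat counting window (s).
#' @param ... passed to [segment_stack()] when `ellipses` is `NULL`.
#' @return An `mmode_metrics` list: `short_VDs_um`, `short_VDd_um`,
#'   `long_VDs_um`, `long_VDd_um`, `EDV_pl`, `ESV_pl`, `SV_pl`, `EF`,
#'   `EF_pct`, `FS_pct`, `mVWVs_um_ms`, `mVWVd_um_ms`,
#'   `heart_rate_bpm`, `n_cycles_used`, and a `detail` sub-list with the
#'   M-mode images, wall traces and extreme points.
#' @export
analyze_mmode <- function(stack, ellipses = NULL,
                          axes = c("principal", "image"), n_cycles = 5,
                          include_pi = FALSE, window_s = 15, ...) {
  axes <- match.arg(axes)
  if (is.null(ellipses)) ellipses <- segment_stack(stack, ...)
  ref <- which.min(ellipses$a_px * ellipses$b_px)   # end-systolic frame
  center <- c(ellipses$cx[ref], ellipses$cy[ref])
  long_angle <- if (axes == "principal") ellipses$theta_deg[ref] else 0
  mm_long <- build_mmode(stack, center, "long", long_angle)
  mm_short <- build_mmode(stack, center, "short", long_angle + 90)
  tr_long <- extract_wall_trace(mm_long)
  tr_short <- extract_wall_trace(mm_short)
  dim_long <- measure_dimensions(tr_long, n_cycles)
  dim_short <- measure_dimensions(tr_short, n_cycles)
  vol <- compute_volumes(dim_short$VDs_um, dim_short$VDd_um,
                         dim_long$VDs_um, dim_long$VDd_um, include_pi)
  effs <- compute_ef_fs(vol$EDV_pl, vol$ESV_pl,
                        dim_short$VDs_um, dim_short$VDd_um)
  pts <- extreme_points(tr_short, n_cycles)
  vel <- wall_velocities(pts)
  hr <- count_heartbeats(tr_short, window_s = window_s)
  structure(c(
    list(short_VDs_um = dim_short$VDs_um, short_VDd_um = dim_short$VDd_um,
         long_VDs_um = dim_long$VDs_um, long_VDd_um = dim_long$VDd_um),
    vol, effs, vel,
    list(heart_rate_bpm = hr$bpm,
         n_cycles_used = min(dim_long$n_cycles_used,
                             dim_short$n_cycles_used),
         detail = list(ellipses = ellipses, reference_frame = ref,
                       mmode_long = mm_long, mmode_short = mm_short,
                       trace_long = tr_long, trace_short = tr_short,
                       extreme_points = pts, heartbeats = hr))),
    class = "mmode_metrics")
}

#' @export
print.mmode_metrics <- function(x, ...) {
  cat("M-mode cardiac metrics\n")
  cat(sprintf("  short VDs/VDd: %.1f / %.1f um;  long VDs/VDd: %.1f / %.1f um\n",
              x$short_VDs_um, x$short_VDd_um, x$long_VDs_um, x$long_VDd_um))
  cat(sprintf("  EDV %.1f pl, ESV %.1f pl, SV %.1f pl\n",
              x$EDV_pl, x$ESV_pl, x$SV_pl))
  cat(sprintf("  EF %.3f (%.1f%%), FS %.1f%%\n", x$EF, x$EF_pct, x$FS_pct))
  cat(sprintf("  mVWVs %.4f, mVWVd %.4f um/ms;  heart rate %.0f bpm\n",
              x$mVWVs_um_ms, x$mVWVd_um_ms, x$heart_rate_bpm))
  invisible(x)
}
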