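# Shared fixtures, all generated in code.

# Logical mask of pixel centers inside an ellipse (no anti-aliasing).
# 0-based center (cx, cy), theta in degrees from the x axis (y down).
make_ellipse_mask <- function(rows, cols, cx, cy, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  xs <- matrix(0:(cols - 1), rows, cols, byrow = TRUE) - cx
  ys <- matrix(0:(rows - 1), rows, cols) - cy
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Small, fast beating-ventricle simulation for property tests.
small_sim <- function(..., n_frames = 50, fps = 20, shape = c(96, 96)) {
  p <- beat_params(a_ed = 30, b_ed = 18, a_es = 24, b_es = 12.6,
                   wall_thickness_um = 5, seed = 42, ...)
  simulate_beating_ventricle(p, n_frames = n_frames, fps = fps,
                             pixel_size = 1, image_shape = shape)
}

# Wall trace with a prescribed width signal, centered on the line.
make_wall_trace <- function(t_ms, width_um) {
  out <- data.frame(frame = seq_along(t_ms), t_ms = t_ms,
                    edge_low_um = -width_um / 2,
                    edge_high_um = width_um / 2,
                    width_um = width_um, flagged = FALSE)
  class(out) <- c("wall_trace", "data.frame")
  out
}

# Ellipse series with constant axes (px) sampled at fps.
constant_ellipse_series <- function(n, a_px, b_px, fps = 20) {
  out <- data.frame(frame = seq_len(n), t_ms = 1000 * (seq_len(n) - 1) / fps,
                    cx = 0, cy = 0, a_px = a_px, b_px = b_px,
                    theta_deg = 0, area_px = pi * a_px * b_px,
                    failed = FALSE)
  class(out) <- c("ellipse_series", "data.frame")
  out
}

# Volume series from an explicit volume signal.
make_volume_series <- function(t_ms, volume_pl) {
  out <- data.frame(t_ms = t_ms, volume_pl = volume_pl)
  class(out) <- c("volume_series", "data.frame")
  out
}
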