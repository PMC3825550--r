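#' Enhance a single frame
#'
#' Contrast/deblur preprocessing ahead of lumen segmentation. Methods:
#' `"none"` (identity), `"background"` (subtract a low intensity quantile,
#' clamp at zero), `"richardson_lucy"` (iterative deconvolution with a
#' Gaussian point-spread function, sharpening the lumen-wall boundary).
#' The enhancement strength (PSF sigma, iteration count) is configuration:
#' no single setting suits every recording.
#'
#' @param frame 2-D numeric matrix.
#' @param method one of `"none"`, `"background"`, `"richardson_lucy"`.
#' @param params list of method parameters: `quantile` (background method,
#'   default 0.25), `sigma` (PSF sd in px, default 1) and `iterations`
#'   (default 10) for Richardson-Lucy.
#' @return Enhanced frame, same shape. `"none"` is the identity;
#'   `"background"` preserves the input scale; `"richardson_lucy"` output
#'   is non-negative on roughly the input scale.
#' @export
enhance_frame <- function(frame, method = c("none", "background",
                                            "richardson_lucy"),
                          params = list()) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop_input("`frame` must be a numeric matrix")
  method <- match.arg(method)
  switch(method,
    none = frame,
    background = {
      q <- params$quantile %||% 0.25
      pmax(frame - stats::quantile(frame, q, names = FALSE), 0)
    },
    richardson_lucy = {
      sigma <- params$sigma %||% 1
      iters <- params$iterations %||% 10L
      eps <- 1e-8
      obs <- pmax(frame, 0)
      est <- obs
      for (k in seq_len(iters)) {
        conv <- EBImage::gblur(est, sigma = sigma)
        est <- est * EBImage::gblur(obs / (conv + eps), sigma = sigma)
      }
      est
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment the bright ventricular lumen in a frame
#'
#' Thresholds the frame (Otsu by default, or a fixed value), keeps the
#' largest connected component of at least `min_area_px` pixels and fills
#' its holes. This automates the manual inner-perimeter tracing step with
#' an operator-free default.
#'
#' @param frame 2-D numeric matrix (enhanced).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param min_area_px minimum component area in pixels.
#' @return A logical mask matrix, or `NULL` when no component of
#'   sufficient area exists (a per-frame segmentation failure, handled by
#'   the caller's interpolation policy).
#' @export
segment_lumen <- function(frame, threshold = "otsu", min_area_px = 25) {
  th <- if (identical(threshold, "otsu")) {
    f01 <- pmax(pmin(frame, 1), 0)
    EBImage::otsu(f01, range = c(0, 1))
  } else if (is.numeric(threshold)) threshold
  else stop_input("`threshold` must be \"otsu\" or a number")
  bw <- frame > th
  if (!any(bw)) return(NULL)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  if (!length(areas) || max(areas) < min_area_px) return(NULL)
  keep <- which.max(areas)
  mask <- lab == keep
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Center of mass of a lumen mask
#'
#' Unweighted centroid of the mask pixels, sub-pixel, in 0-based `(x, y)`
#' coordinates (`x = col - 1`, `y = row - 1`).
#'
#' @param mask logical matrix.
#' @return Named numeric `c(x, y)`.
#' @export
center_of_mass <- function(mask) {
  if (is.null(mask) || !any(mask)) stop_input("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

# Area, centroid and second central moments of a closed polygon
# (Green's theorem; vertices in order, closure implicit).
polygon_moments <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (A == 0) return(list(area = 0))
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Ix2 <- sum((x^2 + x * xn + xn^2) * cr) / 12      # integral of x^2 dA
  Iy2 <- sum((y^2 + y * yn + yn^2) * cr) / 12      # integral of y^2 dA
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = abs(A),
       cx = cx, cy = cy,
       mu20 = Ix2 / A - cx^2,
       mu02 = Iy2 / A - cy^2,
       mu11 = Ixy / A - cx * cy)
}

#' Best-fitting ellipse of a region
#'
#' Matches the second-order central image moments of the region to an
#' ellipse, with area-preserving normalization (the returned ellipse has
#' exactly the region's area): the moment-based "best fitting ellipse" of
#' standard image-analysis practice. Accepts a logical pixel mask or a
#' polygon (data frame with columns `x`, `y`), for which exact polygon
#' moments are used.
#'
#' @param region logical matrix mask, or data frame of polygon vertices.
#' @return An `ellipse_fit` list: `cx`, `cy` (0-based px), `a_px >= b_px`
#'   (semi-axes), `theta_deg` (major-axis orientation in `[0, 180)`
#'   degrees from the x axis, y pointing down; reported as 0 for circles),
#'   `area_px`.
#' @export
fit_ellipse <- function(region) {
  if (is.data.frame(region)) {
    if (!all(c("x", "y") %in% names(region)) || nrow(region) < 3L)
      stop_input("polygon needs columns x, y and >= 3 vertices")
    m <- polygon_moments(region$x, region$y)
    if (m$area <= 0) stop_input("degenerate polygon (zero area)")
  } else {
    if (is.null(region) || !any(region)) stop_input("empty mask")
    idx <- which(region, arr.ind = TRUE)
    xs <- idx[, 2L] - 1; ys <- idx[, 1L] - 1
    cx <- mean(xs); cy <- mean(ys)
    m <- list(area = length(xs), cx = cx, cy = cy,
              mu20 = mean((xs - cx)^2),
              mu02 = mean((ys - cy)^2),
              mu11 = mean((xs - cx) * (ys - cy)))
  }
  tr2 <- (m$mu20 + m$mu02) / 2
  det_rt <- sqrt(((m$mu20 - m$mu02) / 2)^2 + m$mu11^2)
  lam1 <- tr2 + det_rt; lam2 <- tr2 - det_rt
  if (lam2 <= .Machine$double.eps * lam1)
    stop_input("degenerate region: collinear pixels")
  a_raw <- 2 * sqrt(lam1); b_raw <- 2 * sqrt(lam2)
  scale <- sqrt(m$area / (pi * a_raw * b_raw))
  theta <- if (det_rt / tr2 < 1e-9) 0
           else 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02) * 180 / pi
  theta <- theta %% 180
  structure(list(cx = m$cx, cy = m$cy, a_px = a_raw * scale,
                 b_px = b_raw * scale, theta_deg = theta,
                 area_px = m$area), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "ellipse_fit: center (%.2f, %.2f) px, semi-axes %.2f x %.2f px, %.1f deg\n",
    x$cx, x$cy, x$a_px, x$b_px, x$theta_deg))
  invisible(x)
}

#' Segment every frame of a stack and fit per-frame ellipses
#'
#' Runs [enhance_frame()], [segment_lumen()] and [fit_ellipse()] on each
#' frame. Frames on which segmentation fails are flagged and their ellipse
#' parameters linearly interpolated from neighbouring frames, provided no
#' more than `max_fail_frac` of frames fail.
#'
#' @param stack a [frame_stack()].
#' @param enhance_method,enhance_params passed to [enhance_frame()].
#' @param threshold,min_area_px passed to [segment_lumen()].
#' @param max_fail_frac maximum tolerated fraction of failed frames.
#' @return A data frame (class `ellipse_series`) with columns `frame`,
#'   `t_ms`, `cx`, `cy`, `a_px`, `b_px`, `theta_deg`, `area_px`, `failed`.
#' @export
segment_stack <- function(stack, enhance_method = "none",
                          enhance_params = list(), threshold = "otsu",
                          min_area_px = 25, max_fail_frac = 0.1) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  cols <- c("cx", "cy", "a_px", "b_px", "theta_deg", "area_px")
  out <- data.frame(frame = seq_len(n), t_ms = stack$times_ms,
                    cx = NA_real_, cy = NA_real_, a_px = NA_real_,
                    b_px = NA_real_, theta_deg = NA_real_,
                    area_px = NA_real_, failed = FALSE)
  for (i in seq_len(n)) {
    fr <- enhance_frame(get_frame(stack, i), enhance_method, enhance_params)
    mask <- segment_lumen(fr, threshold, min_area_px)
    if (is.null(mask)) { out$failed[i] <- TRUE; next }
    e <- tryCatch(fit_ellipse(mask), error = function(err) NULL)
    if (is.null(e)) { out$failed[i] <- TRUE; next }
    out[i, cols] <- unlist(e[c("cx", "cy", "a_px", "b_px", "theta_deg",
                               "area_px")])
  }
  nfail <- sum(out$failed)
  if (nfail > 0) {
    if (nfail > max_fail_frac * n)
      stop_input(sprintf(
        "segmentation failed on %d/%d frames (more than %.0f%% tolerated)",
        nfail, n, 100 * max_fail_frac))
    ok <- !out$failed
    for (cl in cols)
      out[[cl]][!ok] <- stats::approx(out$frame[ok], out[[cl]][ok],
                                      xout = out$frame[!ok], rule = 2)$y
  }
  class(out) <- c("ellipse_series", "data.frame")
  out
}

#' Fit ellipses to a set of manually traced contours
#'
#' The manual counterpart of [segment_stack()]: applies the moment-based
#' ellipse fit to each traced polygon of a [read_contours()] result.
#'
#' @param contours a `contour_set`.
#' @param fps frame rate used to derive per-frame times.
#' @return An `ellipse_series` data frame (no failed frames).
#' @export
ellipses_from_contours <- function(contours, fps) {
  stopifnot(inherits(contours, "contour_set"))
  frames <- attr(contours, "frames")
  rows <- lapply(seq_along(contours), function(i) {
    e <- fit_ellipse(contours[[i]])
    data.frame(frame = frames[i], t_ms = 1000 * frames[i] / fps,
               cx = e$cx, cy = e$cy, a_px = e$a_px, b_px = e$b_px,
               theta_deg = e$theta_deg, area_px = e$area_px,
               failed = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ellipse_series", "data.frame")
  out
}
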