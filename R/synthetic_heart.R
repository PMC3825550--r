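#' Beating-ventricle simulation parameters
#'
#' Defines the forward model of a periodically contracting elliptical
#' ventricle imaged with a bright-lumen vital dye: a filled ellipse of
#' intensity `i_lumen` (plasma), surrounded by a darker myocardial ring of
#' intensity `i_wall` and thickness `wall_thickness_um`, on background
#' `i_bg`. Semi-axes interpolate between end-diastole and end-systole
#' following a periodic contraction profile `s(t) %in% [0, 1]` (0 =
#' end-diastole, 1 = end-systole).
#'
#' Defaults model a ~60 hpf embryonic zebrafish ventricle: long/short
#' end-diastolic semi-axes 50/30 um, end-systolic 40/21 um, a 500 ms cycle
#' (120 bpm, ~2 Hz) and a systolic fraction of 0.4.
#'
#' @param period_ms cardiac cycle length in ms.
#' @param a_ed,b_ed end-diastolic long/short semi-axes (um).
#' @param a_es,b_es end-systolic long/short semi-axes (um); must be smaller
#'   than their diastolic counterparts.
#' @param systole_fraction fraction of the cycle spent contracting, in (0,1).
#' @param waveform `"raised_cosine"`: raised-cosine contraction over
#'   `systole_fraction * period` followed by raised-cosine relaxation (C^1
#'   periodic, analytically differentiable).
#' @param orientation_deg long-axis orientation, degrees counterclockwise
#'   from the image x axis (y pointing down), in `[0, 180)`.
#' @param center_drift_um_s translation speed of the ventricle center
#'   (applied along +x), um/s.
#' @param i_lumen,i_wall,i_bg intensities of lumen, wall ring and
#'   background on the `[0, 1]` scale; `i_lumen > i_wall >= i_bg`.
#' @param wall_thickness_um myocardial ring thickness (um).
#' @param noise_sd additive Gaussian noise SD (applied after blur).
#' @param blur_sigma_px Gaussian optical blur SD in pixels.
#' @param seed RNG seed for the noise; identical seeds give bit-identical
#'   stacks.
#' @return A `beat_params` list.
#' @export
beat_params <- function(period_ms = 500, a_ed = 50, b_ed = 30,
                        a_es = 40, b_es = 21, systole_fraction = 0.4,
                        waveform = "raised_cosine", orientation_deg = 0,
                        center_drift_um_s = 0, i_lumen = 1, i_wall = 0.25,
                        i_bg = 0.05, wall_thickness_um = 8,
                        noise_sd = 0, blur_sigma_px = 1, seed = NULL) {
  check_positive_scalar(period_ms, "period_ms")
  if (!(a_ed >= a_es && a_es > 0)) stop_input("need a_ed >= a_es > 0")
  if (!(b_ed >= b_es && b_es > 0)) stop_input("need b_ed >= b_es > 0")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop_input("systole_fraction must be in (0, 1)")
  if (!(i_lumen > i_wall)) stop_input("need i_lumen > i_wall")
  if (!(i_wall >= i_bg && i_bg >= 0)) stop_input("need i_wall >= i_bg >= 0")
  if (noise_sd < 0 || blur_sigma_px < 0)
    stop_input("noise_sd and blur_sigma_px must be >= 0")
  waveform <- match.arg(waveform, "raised_cosine")
  structure(list(
    period_ms = period_ms, a_ed = a_ed, b_ed = b_ed, a_es = a_es,
    b_es = b_es, systole_fraction = systole_fraction, waveform = waveform,
    orientation_deg = orientation_deg, center_drift_um_s = center_drift_um_s,
    i_lumen = i_lumen, i_wall = i_wall, i_bg = i_bg,
    wall_thickness_um = wall_thickness_um, noise_sd = noise_sd,
    blur_sigma_px = blur_sigma_px, seed = seed), class = "beat_params")
}

# Contraction profile s(t) and its derivative (per ms): raised-cosine
# systole over f*T, raised-cosine relaxation over (1-f)*T.
contraction_profile <- function(p) {
  T <- p$period_ms; f <- p$systole_fraction
  s <- function(t_ms) {
    t <- t_ms %% T
    ifelse(t < f * T,
           (1 - cos(pi * t / (f * T))) / 2,
           (1 + cos(pi * (t - f * T) / ((1 - f) * T))) / 2)
  }
  ds <- function(t_ms) {
    t <- t_ms %% T
    ifelse(t < f * T,
           pi / (2 * f * T) * sin(pi * t / (f * T)),
           -pi / (2 * (1 - f) * T) * sin(pi * (t - f * T) / ((1 - f) * T)))
  }
  list(s = s, ds = ds)
}

#' Ventricular volume from semi-axes
#'
#' The prolate-spheroid volume used throughout: by default the literal
#' formula `4 a b^2 / 3` (in um^3, reported in pl; 1 pl = 1000 um^3),
#' with `include_pi = TRUE` giving the geometric ellipsoid-of-revolution
#' volume `(4/3) pi a b^2`.
#'
#' @param a_um long semi-axis (um).
#' @param b_um short semi-axis (um).
#' @param include_pi include the factor pi.
#' @return Volume in picolitres.
#' @export
volume_from_axes <- function(a_um, b_um, include_pi = FALSE) {
  v <- 4 * a_um * b_um^2 / 3
  if (include_pi) v <- v * pi
  v / 1000
}

#' Simulate a fluorescence video of a beating ventricle
#'
#' Renders each frame as an anti-aliased (4x supersampled) filled ellipse
#' with time-varying semi-axes `a(t) = a_ed - (a_ed - a_es) s(t)` (likewise
#' `b`), a darker wall ring, Gaussian optical blur, then additive Gaussian
#' noise. Returns the stack together with the analytic ground truth of
#' every quantity the analysis modules estimate.
#'
#' @param p a [beat_params()] object.
#' @param n_frames number of frames to render.
#' @param fps frame rate (frames/second).
#' @param pixel_size microns per pixel.
#' @param image_shape `c(rows, cols)` of each frame in pixels.
#' @param include_pi volume formula flag passed to [volume_from_axes()]
#'   for the ground-truth volumes.
#' @return A list with `stack` (a [frame_stack()]) and `truth` (per-frame
#'   data frame plus scalar EDV/ESV/SV/EF/FS/heart-rate/peak-rate truths).
#' @export
simulate_beating_ventricle <- function(p, n_frames = 100, fps = 20,
                                       pixel_size = 1,
                                       image_shape = c(128, 128),
                                       include_pi = FALSE) {
  stopifnot(inherits(p, "beat_params"))
  if (n_frames < 2L) stop_input("need at least 2 frames")
  rows <- image_shape[1L]; cols <- image_shape[2L]
  t_ms <- 1000 * (seq_len(n_frames) - 1) / fps
  prof <- contraction_profile(p)
  s_t <- prof$s(t_ms)
  a_t <- p$a_ed - (p$a_ed - p$a_es) * s_t
  b_t <- p$b_ed - (p$b_ed - p$b_es) * s_t

  cx0 <- (cols - 1) / 2; cy0 <- (rows - 1) / 2        # px
  drift_px_ms <- p$center_drift_um_s / 1000 / pixel_size
  cx_t <- cx0 + drift_px_ms * t_ms
  cy_t <- rep(cy0, n_frames)
  reach_px <- (p$a_ed + p$wall_thickness_um) / pixel_size
  if (any(cx_t - reach_px < 0 | cx_t + reach_px > cols - 1) ||
      any(cy_t - reach_px < 0 | cy_t + reach_px > rows - 1))
    stop_input("ellipse plus wall ring exceeds the frame; enlarge ",
               "image_shape or reduce the axes/drift")

  th <- p$orientation_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  xs <- (0:(4 * cols - 1)) * 0.25 - 0.375              # subpixel x coords
  ys <- (0:(4 * rows - 1)) * 0.25 - 0.375
  w_um <- p$wall_thickness_um

  render <- function(i) {
    a_px <- a_t[i] / pixel_size; b_px <- b_t[i] / pixel_size
    aw_px <- (a_t[i] + w_um) / pixel_size
    bw_px <- (b_t[i] + w_um) / pixel_size
    dx <- matrix(xs - cx_t[i], nrow = 4 * rows, ncol = 4 * cols, byrow = TRUE)
    dy <- matrix(ys - cy_t[i], nrow = 4 * rows, ncol = 4 * cols)
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    lumen <- (u / a_px)^2 + (v / b_px)^2 <= 1
    wall <- (u / aw_px)^2 + (v / bw_px)^2 <= 1
    sub <- p$i_bg + wall * (p$i_wall - p$i_bg) + lumen * (p$i_lumen - p$i_wall)
    downsample4 <- function(m) {
      r4 <- dim(m)[1L] / 4; c4 <- dim(m)[2L] / 4
      m1 <- colMeans(array(m, dim = c(4, r4, 4 * c4)))     # r4 x 4c
      t(colMeans(array(t(m1), dim = c(4, c4, r4))))        # r4 x c4
    }
    fr <- downsample4(sub)
    if (p$blur_sigma_px > 0) fr <- EBImage::gblur(fr, sigma = p$blur_sigma_px)
    fr
  }

  frames <- array(0, dim = c(rows, cols, n_frames))
  with_seed(p$seed, {
    for (i in seq_len(n_frames)) {
      fr <- render(i)
      if (p$noise_sd > 0)
        fr <- fr + matrix(rnorm(rows * cols, sd = p$noise_sd), rows, cols)
      frames[, , i] <- fr
    }
  })
  stack <- frame_stack(frames, fps = fps, pixel_size = pixel_size)

  vol_t <- volume_from_axes(a_t, b_t, include_pi)
  edv <- volume_from_axes(p$a_ed, p$b_ed, include_pi)
  esv <- volume_from_axes(p$a_es, p$b_es, include_pi)
  # analytic dV/dt (pl/ms) on a fine grid over one cycle
  tg <- seq(0, p$period_ms, length.out = 20001)
  sg <- prof$s(tg); dsg <- prof$ds(tg)
  ag <- p$a_ed - (p$a_ed - p$a_es) * sg
  bg <- p$b_ed - (p$b_ed - p$b_es) * sg
  dag <- -(p$a_ed - p$a_es) * dsg
  dbg <- -(p$b_ed - p$b_es) * dsg
  cvol <- if (include_pi) 4 * pi / 3 else 4 / 3
  dV <- cvol * (dag * bg^2 + 2 * ag * bg * dbg) / 1000
  truth <- list(
    per_frame = data.frame(frame = seq_len(n_frames), t_ms = t_ms,
                           a_um = a_t, b_um = b_t, cx_px = cx_t,
                           cy_px = cy_t, volume_pl = vol_t),
    EDV_pl = edv, ESV_pl = esv, SV_pl = edv - esv, EF = (edv - esv) / edv,
    FS_pct = 100 * (p$b_ed - p$b_es) / p$b_ed,
    heart_rate_bpm = 60000 / p$period_ms,
    peak_ejection_rate_pl_ms = min(dV),
    peak_filling_rate_pl_ms = max(dV),
    period_ms = p$period_ms, include_pi = include_pi)
  list(stack = stack, truth = truth)
}

#' Morphant-cohort simulation parameters
#'
#' Emulates a fluorophore-tracked knockdown experiment: each embryo is
#' co-injected with a lissamine-labelled control morpholino whose
#' fluorescence intensity (FI) proxies the delivered dose of the targeting
#' morpholino. FI is log-normal across embryos (injection variability);
#' true relative target expression decays as `exp(-k * FI)`; the measured
#' expression ratio carries multiplicative log-normal noise; the cardiac
#' phenotype follows thresholds on true expression.
#'
#' @param n cohort size.
#' @param fi_meanlog,fi_sdlog log-normal parameters of the FI distribution.
#' @param knockdown_slope decay rate `k` of expression with FI; `k = 0`
#'   means no knockdown.
#' @param noise_sdlog SD of the multiplicative log-normal measurement noise
#'   on the expression ratio.
#' @param phenotype_thresholds named vector
#'   `c(no_cardiac_output = lo, congestion = hi)`: true expression `<= lo`
#'   gives no cardiac output, `(lo, hi]` congestion, `> hi` no phenotype.
#' @param seed RNG seed; fixed seed gives an identical table.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n = 300, fi_meanlog = log(2.5), fi_sdlog = 0.7,
                          knockdown_slope = 0.2, noise_sdlog = 0.2,
                          phenotype_thresholds = c(no_cardiac_output = 0.3,
                                                   congestion = 0.55),
                          seed = NULL) {
  if (n < 1L) stop_input("n must be >= 1")
  if (knockdown_slope < 0) stop_input("knockdown_slope must be >= 0")
  if (noise_sdlog < 0) stop_input("noise_sdlog must be >= 0")
  if (length(phenotype_thresholds) != 2L ||
      diff(phenotype_thresholds) <= 0)
    stop_input("phenotype_thresholds must be two increasing values")
  structure(list(n = n, fi_meanlog = fi_meanlog, fi_sdlog = fi_sdlog,
                 knockdown_slope = knockdown_slope,
                 noise_sdlog = noise_sdlog,
                 phenotype_thresholds = phenotype_thresholds, seed = seed),
            class = "cohort_params")
}

#' Simulate a morphant cohort
#'
#' @param p a [cohort_params()] object.
#' @return A data frame with one row per embryo: `id`, `fi`,
#'   `true_expression`, `expression_ratio` (noisy measurement), `phenotype`
#'   (factor: `no_phenotype`, `congestion`, `no_cardiac_output`) and
#'   `group`.
#' @export
simulate_morphant_cohort <- function(p) {
  stopifnot(inherits(p, "cohort_params"))
  with_seed(p$seed, {
    fi <- rlnorm(p$n, meanlog = p$fi_meanlog, sdlog = p$fi_sdlog)
    true_expr <- exp(-p$knockdown_slope * fi)
    ratio <- true_expr * rlnorm(p$n, meanlog = 0, sdlog = p$noise_sdlog)
  })
  lo <- p$phenotype_thresholds[[1L]]; hi <- p$phenotype_thresholds[[2L]]
  phen <- ifelse(true_expr <= lo, "no_cardiac_output",
                 ifelse(true_expr <= hi, "congestion", "no_phenotype"))
  data.frame(
    id = sprintf("embryo_%03d", seq_len(p$n)),
    fi = fi, true_expression = true_expr, expression_ratio = ratio,
    phenotype = factor(phen, levels = c("no_phenotype", "congestion",
                                        "no_cardiac_output")),
    group = "morphant")
}
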