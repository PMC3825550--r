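---
title: "Measuring embryonic zebrafish cardiac function from bright-lumen fluorescence video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring embryonic zebrafish cardiac function from bright-lumen fluorescence video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfcardio)
```

## The measurement problem

The embryonic zebrafish heart is transparent: in bright-field video the
boundary between the myocardial wall and the blood-filled lumen is nearly
invisible, which makes chamber dimensions — and everything derived from
them — unreliable. Staining the circulating plasma with a vital dye such as
Bodipy-ceramide inverts the contrast: the ventricular lumen becomes a bright
ellipse-like region against a dark wall, and its boundary can be localized
precisely in every frame of a fluorescence time-lapse recording (typically
about 20 frames per second for a few seconds, at around 1 µm/pixel).

`zfcardio` turns such recordings into quantitative cardiac function
measurements through two complementary routes:

1. **M-mode analysis.** A fixed single-pixel-wide line is placed through the
   ventricular center of mass and sampled in every frame, producing a
   position × time "pseudo-linescan" image. The moving inner-wall edges trace
   bright/dark bands whose extremal separations give the end-systolic and
   end-diastolic internal dimensions (VDs, VDd) along the long and short
   axes; volumes, ejection fraction, fractional shortening, wall velocities
   and heart rate follow.
2. **Time–volume-curve (TVC) analysis.** The lumen is delineated in every
   frame, a best-fitting ellipse extracted, and a per-frame volume computed;
   a truncated five-harmonic Fourier series fitted to this series yields a
   smooth periodic volume curve whose analytic derivative supplies the
   ejection- and filling-phase indices (peak and first-third rates, times to
   peak, first-third fractions).

Both routes are validated end to end against a forward simulator of a
beating elliptical ventricle with exact analytic ground truth.

## Geometry, conventions, units

Frames are numeric matrices indexed `[row, col]` on a common intensity scale
of `[0, 1]`. Continuous image coordinates are 0-based with `x = col − 1`,
`y = row − 1` and pixel centers at integers; one stated convention avoids
off-by-one drift between segmentation, M-mode placement and the simulator.
Orientations are degrees counterclockwise from the x axis *with y pointing
down* (i.e., clockwise on screen), reported in `[0°, 180°)`, ties (circles)
reported as 0°. Lengths are µm (`pixel_size` µm/pixel), times ms, volumes
picolitres (1 pl = 10³ µm³), rates pl/ms, wall velocities µm/ms.

Frame timing is uniform, `t = 1000·(index − 1)/fps` ms: the camera delivers
an approximately constant frame rate and no per-frame timestamps, so derived
timing is the default; explicit timestamps can be supplied to
`frame_stack()`.

## Volume model

Volumes use the prolate-spheroid formula in its literal form

$$V = \frac{4\,a\,b^2}{3},$$

with `a` the long and `b` the short semi-axis. The geometric volume of an
ellipsoid of revolution carries an additional factor of π; the default here
is deliberately the literal formula so that results are directly comparable
with the established workflow this package reproduces, and
`include_pi = TRUE` switches every volume-producing function to the
π-corrected form. Because EF, %FS, 1/3EF and 1/3FF are ratios of volumes or
dimensions, they are identical under either convention; only absolute
volumes (EDV, ESV, SV) and rates change by the factor π.

## Segmentation and the best-fitting ellipse

The original workflow traces the inner perimeter of the ventricle by hand.
`zfcardio` preserves that route (`read_contours()` +
`ellipses_from_contours()`) but defaults to an operator-free automation:

* optional enhancement (`enhance_frame()`): background subtraction or
  Richardson–Lucy deconvolution with a Gaussian PSF. The enhancement
  strength (PSF σ, iteration count) is configuration, not a fixed constant —
  recordings differ too much in optics for one setting to be right;
* Otsu (or fixed) thresholding, retention of the largest connected
  component above a minimum area, hole filling (`segment_lumen()`);
* the **moment-based best-fitting ellipse** (`fit_ellipse()`): second-order
  central moments of the region are matched to an ellipse, then rescaled so
  the ellipse area equals the region area exactly (area-preserving
  normalization, as in the standard ImageJ "fit ellipse"). For traced
  polygons the moments are computed exactly by Green's theorem rather than
  by rasterization.

Frames where segmentation fails (no sufficiently large bright component)
are flagged and their ellipse parameters linearly interpolated from
neighbours, provided no more than 10 % of frames fail; M-mode and TVC
analysis need a value in every frame, and a stricter policy would make
short recordings unusable for transient specks of noise.

## M-mode analysis

The reference frame is the end-systolic one (smallest fitted lumen), whose
center of mass anchors both lines. By default the lines follow the
*principal axes* of the reference ellipse; `axes = "image"` restores strict
horizontal/vertical lines, which assume the standard ventral mounting of
the embryo. Axis-aligned lines through an integer center reduce to exact
row/column extraction; oblique lines are sampled bilinearly.

Wall edges are localized per M-mode column as **half-maximum crossings** of
the Gaussian-smoothed (σ = 1 px) intensity profile, walking outward from
the center: sub-pixel, parameter-light, and exact for a blurred step edge
(Gaussian blur moves a step's half-maximum crossing by zero). The edge
definition is a design choice of this package; it was selected over
gradient-extremum localization because it is robust at the modest
signal-to-noise of dye-labelled recordings.

Per-cycle extrema of the lumen width are found by prominence-filtered peak
detection (prominence ≥ half the width range, plateau ties broken by
earliest time) with three-point quadratic refinement. VDs and VDd are means
over five systoles and diastoles by default. Wall velocities use the
classic 11-point scheme — six maximal inward and five maximal outward
excursions of the ventral wall, alternating — generalized to `n + 1` inward
and `n` outward points for `n` cycles: each systolic slope is
|Δposition/Δtime| across an outward→inward pair, each diastolic slope
across an inward→outward pair, and mVWVs/mVWVd are the means of five slopes
each.

**Heart rate.** The reference method counts beats over a 15 s window. A
finite window bounded by partial cycles biases a naive interior-maximum
count (a 2 Hz beat over exactly 15 s has 29 interior width maxima but 30
beats), so `count_heartbeats()` estimates the cycle length as the mean of
quadratically refined inter-peak intervals and reports
`round(window/period)` beats with the corresponding bpm; recordings shorter
than the window report the rate extrapolated from the observed cycle
length, flagged as such.

## Time–volume curve analysis

The per-frame ellipse axes give a volume sample per frame. The fundamental
period is taken from the dominant nonzero-frequency peak of the discrete
spectrum, refined by local quadratic interpolation of the magnitude (and
can be overridden). The five-harmonic least-squares fit is linear; one
numerical subtlety matters at cardiac rates: at 20 fps the Nyquist
frequency is 10 Hz, and for cycle lengths of 400–500 ms the fourth or fifth
harmonic reaches or exceeds it. Super-Nyquist harmonic columns alias
*exactly* onto lower ones and are therefore excluded from the design (their
coefficients reported as zero) rather than left to floating-point-fragile
rank detection. Consequently the five-harmonic model is fully identified
only for cycles longer than 500 ms at 20 fps; tests and simulations that
exercise exact coefficient recovery use a 600 ms cycle.

All TVC parameters derive from the fitted curve on a dense grid (period /
2048, quadratically refined): end-diastole `t_ED` at the (earliest) global
maximum `V1`, end-systole `t_ES` at the following minimum `V2`; ejection
spans `[t_ED, t_ES]` and filling the remainder. `V3` and `V4` are the
volumes one third into each phase; `D1`/`D2` the extreme analytic
derivatives during ejection/filling with `TD1`/`TD2` their delays from
phase onset; `D3`/`D4` the mean derivatives over each first third. Derived
indices follow the standard radionuclide-ventriculography formula set (EF,
1/3EF, 1/3FF as percentages; TPE = TD1, TPF = TD2;
PER = −D1·1000/V1, PFR = D2·1000/V1 and the first-third analogues). Two
printed conventions are ambiguous and both readings are available: the
first-third filling rate defaults to `D4·1000/V1` (dimensionally consistent
with its ejection counterpart), with the literal alternative
`D4·1000/(T·V1)` behind `literal_one_third_fr = TRUE`; and because
EDV-normalized "rates" are really s⁻¹, the raw `D1..D4` in pl/ms are
returned alongside the normalized indices.

## The synthetic beating ventricle

`simulate_beating_ventricle()` renders, per frame, a filled ellipse
(intensity `i_lumen`) inside a darker myocardial ring (`i_wall`, thickness
`wall_thickness_um`) on background `i_bg`, with semi-axes

$$a(t) = a_{ED} - (a_{ED} - a_{ES})\,s(t),$$

where `s(t)` is a C¹ periodic raised-cosine profile: contraction over
`systole_fraction · T`, relaxation over the remainder. Edges are
anti-aliased by 4× supersampling, then Gaussian optical blur, then additive
Gaussian noise (in that order, so the σ → 0 limit retains the closed-form
truth). A fixed seed gives bit-identical stacks. Ground truth includes the
per-frame axes, center and volume and the scalar EDV, ESV, SV, EF, %FS,
heart rate and analytic peak ejection/filling rates.

Defaults model a ~60 hpf embryo: 500 ms cycle (120 bpm; embryonic rates run
near 2 Hz), end-diastolic semi-axes 50/30 µm and end-systolic 40/21 µm
(EF ≈ 0.61), systolic fraction 0.4, 8 µm wall, intensity triplet
1/0.25/0.05, blur σ 1 px, 20 fps, 1 µm/pixel, 128×128 frames. These values
were fixed once as the study conditions for all validation.

What the simulator deliberately does *not* model: atrium and valves,
red-blood-cell speckle inside the lumen, non-Gaussian optics, out-of-plane
motion, photobleaching, and irregular rhythm. Passing recovery tests on
simulated video therefore demonstrates the correctness of the measurement
chain (segmentation → ellipse → M-mode/TVC → indices) under the stated
imaging model, not robustness to every artefact of live microscopy; the
manual-contour route exists precisely for recordings the automation cannot
handle.

`simulate_morphant_cohort()` emulates the fluorophore-tracked knockdown
design: per-embryo fluorescence intensity (FI) of a co-injected
lissamine-labelled control morpholino proxies the delivered dose, drawn
log-normal (meanlog log 2.5, sdlog 0.7 — a spread that populates all four
conventional FI bins and guarantees low-FI controls); true relative target
expression decays as `exp(−k·FI)` with `k = 0.2`; measured expression
ratios carry multiplicative log-normal noise (sdlog 0.2); phenotype class
(none / venous congestion / no cardiac output) follows thresholds (0.55,
0.3) on true expression.

## Dose statistics

`bin_by_fi()` uses half-open bins with inclusive lower edges (default
edges 2, 4, 8, last bin unbounded). `normalize_expression()` divides every
expression ratio by the mean ratio of low-FI controls (FI < 1), mapping the
control mean to exactly 1. `spearman_corr()` uses average ranks for ties
and an exhaustive-permutation two-sided p value for n ≤ 9 (t approximation
above). Group comparisons are pooled-variance Student's t tests (Welch
optional), pairwise with Bonferroni adjustment
`min(1, p · #comparisons)` — the most common reading of a "Bonferroni
multiple comparisons test", recorded as such in the output. The 2×2
contingency test is the Pearson chi-square without continuity correction by
default (Yates optional): on the rescue-experiment counts an uncorrected
test is the plain reading of "chi-square test", and the conclusion is
insensitive to the choice.

## Numerical choices and degenerate inputs

* Peak detection is deterministic: strict local maxima, plateaus counted
  once at their earliest sample, prominence thresholds expressed as a
  fraction of the signal range (default 0.5).
* All extremum locations (trace extrema, TVC extrema, spectral peaks) are
  refined by three-point quadratic interpolation, clamped to ±half a grid
  step.
* Degenerate cases error loudly rather than guessing: empty masks,
  collinear regions, flat volume series, monotone fitted curves, constant
  vectors in rank correlation, zero contingency margins. Two conventions
  are silent by design: a zero-variance t test with equal means returns
  p = 1, and a circle's orientation is 0°.
* A static simulation (equal ED and ES axes) is allowed as a degenerate
  test case even though a beating heart requires strict contraction.

## Problem sizes used in validation

The packaged tests and the acceptance script analyse simulated videos of
55–65 frames (≥ 5 cycles at 20 fps) at 128×128 px — the scale of a real
5 s recording — plus cohorts of n = 300 over up to 100 seeds, and
exhaustive oracle checks over all 2×2 tables with margins ≤ 6 and all
permutations of up to 7 paired samples. These sizes were chosen to exercise
every code path at realistic acquisition scale.

## Known limitations

* The M-mode line is fixed for the whole recording; large ventricular
  drift (more than a few µm/s) degrades dimension estimates before the
  segmentation route does.
* The five-harmonic TVC model underestimates peak rates for very sharp
  systoles (high harmonic content), and at 20 fps cannot resolve all five
  harmonics for cycles at or below 500 ms (see above).
* Half-maximum edge localization assumes the lumen is the brightest
  structure on the line; a line crossing the atrium or bulbus would need
  the manual-contour route.
* The EDV-normalized "rates" (PER, PFR, 1/3ER, 1/3FR) follow the
  conventional but dimensionally loose printed definitions; raw pl/ms
  values are provided for physically meaningful comparisons.
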