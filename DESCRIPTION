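Package: zfcardio
Title: Fluorescence-Based Cardiac Function Analysis for Embryonic Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies ventricular function of the embryonic zebrafish heart
    from time-lapse fluorescence microscopy of a dye-labelled (bright-lumen)
    ventricle. Provides M-mode pseudo-linescan construction through the
    ventricular center of mass with extraction of end-systolic and
    end-diastolic dimensions, prolate-spheroid volumes, ejection fraction,
    fractional shortening, wall velocities and heart rate; per-frame
    time-volume curves with truncated five-harmonic Fourier fitting and the
    derived ejection/filling indices (1/3EF, 1/3FF, TPE, TPF, PER, PFR and
    their first-third counterparts); and dose-response statistics for
    fluorophore-tracked morpholino knockdown cohorts (fluorescence-intensity
    binning, expression normalization, rank correlation, Bonferroni-adjusted
    pairwise t tests, contingency tests). A forward simulator of a beating
    elliptical ventricle and of morphant cohorts supplies ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
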