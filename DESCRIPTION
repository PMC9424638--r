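Package: sspt
Title: Analysis of Light-Induced Solid-to-Solid Phase Transitions in
    Riboswitch Crystals by Polarized Video Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify light-induced solid-to-solid phase
    transitions (SSPT) in adenine-riboswitch crystals observed by
    time-lapse polarized video microscopy (PVM).  Provides a synthetic
    video generator with per-pixel ground-truth transition times, the
    intensity-trace pipeline (region-of-interest cropping, superpixel
    binning, boxcar smoothing, first derivatives, transition-time and
    half-width extraction, k-means classification), a forward four-state
    mass-action model of ligand-driven conformational switching with
    inflection-time extraction and reproducible least-squares fitting,
    and the photochemistry arithmetic for photocaged-ligand uncaging
    (HPLC standard curves, percent release, beam power density,
    illuminated drop fraction, nominal uncaged concentration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
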