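Package: patchtension
Title: Membrane Tension and Mechanosensitive Channel Gating from Patch-Clamp
    Imaging and Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies activation of mechanosensitive ion channels (TRAAK,
    TREK-1, TREK-2, MscS and similar) by membrane tension from simultaneous
    patch-clamp recording and patch fluorescence imaging. Detects the membrane
    arc in fluorescence frames (brightest pixel per row with continuity
    filtering), fits its radius of curvature by exact three-point and algebraic
    least-squares circle fits, converts applied pressure and radius to membrane
    tension via the Young-Laplace relation, extracts and normalizes peak
    currents per stimulus step, fits two-state Boltzmann tension-response
    curves (per patch or globally) with confidence intervals, and derives
    channel energetics (in-plane area expansion and gating free energy).
    Includes hydrophone-based ultrasound acoustic intensity calculation and
    power-domain dose-response fitting, and a synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
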