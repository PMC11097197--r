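Package: hemoveloc
Title: Synthetic Pulsatile-Flow Phantoms, Particle Image Velocimetry, and
    Vector-Derived Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for benchmarking vector flow imaging of the femoral
    bifurcation. Generates synthetic pulsatile flow phantoms with known ground
    truth (triphasic femoral waveforms, Womersley and Poiseuille profiles, an
    analytic stenotic-jet field, rendered tracer-particle image sequences with
    optional low-rank clutter), estimates velocity fields by multi-pass
    normalized cross-correlation particle image velocimetry with optical- and
    echo-style pipeline presets, removes clutter by singular value
    decomposition of the Casorati matrix, derives hemodynamic parameters
    (volumetric flow rate, vector complexity, time-averaged wall shear stress,
    Reynolds number, Kolmogorov length), and quantifies inter-modality
    agreement with Bland-Altman limits of agreement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
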