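Package: motormap
Title: Quantitative Mapping of Cortical Muscle Representations from Navigated TMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs three-dimensional response surfaces ("motor maps") over a sphere
    fitted to navigated transcranial magnetic stimulation (TMS) coordinates, using either
    an exact smooth interpolation or an exponential-kernel construction, and derives the
    quantitative descriptors used in TMS motor mapping: representation areas, volumes,
    centers of gravity, hotspots, overlap maps, and a normalized Earth Mover's Distance
    between excitability profiles with a geodesic ground metric. Includes readers and
    writers for stimulation-session spreadsheets and a navigation-text dialect, NIfTI
    anatomy loading, color-coded 2D map rendering, and a synthetic-session generator with
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    readxl,
    zip,
    png,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
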