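Package: rodcoords
Title: Curvilinear Coordinate Systems for Rod-Shaped Bacterial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds a per-cell curvilinear coordinate system for rod-shaped
    bacteria such as Escherichia coli. Each cell is described by a quadratic
    midline, its endpoints and a radius; Cartesian pixel coordinates and
    single-molecule localization (SMLM/STORM) coordinates are transformed to
    cellular coordinates (longitudinal position, radial distance, angle) and
    back. The coordinate system is refined by minimizing chi-square objective
    functions against binary masks, brightfield images or membrane-marker
    localizations. On top of the transform the package provides radial,
    longitudinal and angular distributions, multi-cell alignment onto a model
    cell, membrane periodicity analysis by autocorrelation and Fourier
    transform, and a fully seeded synthetic-cell benchmark with Poisson shot
    noise and Gaussian read noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
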