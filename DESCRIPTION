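Package: kfactor3d
Title: K-Factor Image Deshadowing for 3D Single-Molecule Localization
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear K-factor image decomposition and deshadowing for
    three-dimensional fluorescence z-stacks. Factorizes each image plane
    into a product of binary contrast factors with a decreasing
    contrast-depth schedule, multiplies the image by its factors to narrow
    point-spread functions and suppress background, and couples this with
    Gaussian and Gibson-Lanni point-spread-function simulators, 3D
    least-squares single-emitter localization, and Monte Carlo harnesses
    for localization precision and two-emitter resolvability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
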