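Package: panosim
Title: Panoramic Structured Illumination Microscopy Reconstruction and Stitching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for panoramic (tiled mosaic) structured
    illumination microscopy (SIM). Simulates or ingests phase-stepped
    patterned-illumination tile stacks, reconstructs wide-field, optically
    sectioned (OS-SIM) and super-resolved maximum a posteriori (MAP-SIM)
    images per tile, estimates and removes the SIM-induced vignette by
    dividing tiles by a blurred average intensity projection, stitches the
    tile grid with optional phase-correlation offset refinement and feather
    blending, and quantifies image resolution via the noise-corrected
    radially averaged power spectral density cut-off as well as residual
    grid artifacts via FFT peaks at the stitching period.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
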