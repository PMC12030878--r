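Package: mwcamera
Title: Quantitative Microwave Breast Imaging with Spectral Backpropagation and U-Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imaging chain of a planar microwave camera for anthropomorphic breast
    phantoms immersed in water. Generates a combinatorial phantom database, simulates
    the z-polarized scattered field on the 64x64 camera retina (Born angular-spectrum
    solver, plus an optional 2D full-wave volume-integral solver), applies the Fourier
    diffraction theorem to extract and filter the induced-current spectrum, and trains
    a pair of small U-Nets that translate the filtered current spectrum into a
    dielectric-contrast spectrum, from which relative permittivity and conductivity
    maps are calibrated against the known coupling medium. Includes SSIM/PSNR
    evaluation and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
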