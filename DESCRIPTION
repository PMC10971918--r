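Package: cceit
Title: Simulated Capacitively Coupled Electrical Impedance Tomography of
    Brain Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying image reconstruction in capacitively coupled
    electrical impedance tomography (CCEIT) of stroke. Provides a
    constraint-driven generator of two-dimensional ellipse-based head phantoms
    with hemorrhagic and ischemic lesions, a finite-volume forward solver for
    the complex-permittivity quasi-static field of an insulated 16-electrode
    sensor belt, linearized sensitivity-matrix baselines (linear back
    projection and truncated pseudoinverse), a conditional adversarial
    neural-network reconstructor mapping complex capacitance frames to
    conductivity images, and the image-quality metrics used to evaluate
    reconstructions (RMSE, PSNR, SSIM, 2D correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr
Config/testthat/edition: 3
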