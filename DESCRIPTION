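Package: deerpop
Title: Conformational Population Analysis of DEER Distance Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and inversion of four-pulse double electron-electron
    resonance (DEER/PELDOR) dipolar traces for intrinsically disordered
    proteins.  Provides the powder-averaged dipolar kernel in closed Fresnel
    form, synthetic trace generation from Gaussian-mixture distance
    distributions with intermolecular background and noise, background
    correction, non-negative Tikhonov inversion with L-curve regularization
    parameter selection and maximum-entropy refinement, and constrained one-
    or two-Gaussian fitting of the reconstructed distance distributions to
    quantify compact (S) versus extended (S*) conformer populations over an
    aggregation time course.  Includes a freely-jointed/self-avoiding chain
    ensemble generator for site-pair distance histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
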