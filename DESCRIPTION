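Package: stemdiff
Title: Diffusion-Distribution Modelling of Beam Damage in Scanning
    Transmission Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form and quadrature solutions of Fick's-law diffusion from
    instantaneous, continuous point, circular-disc, square-disc and Gaussian
    electron-probe sources; accumulation of per-probe distributions into
    cumulative diffusion distribution (CDD) maps over arbitrary scan
    trajectories with dwell, settling and blanking times; point-wise and
    global maximum CDD statistics; threshold-based diffusion-induced damage
    (DID) models with sign/ReLU activations and offline/online pupils;
    compressive subsampling (uniform density and linehop masks, beam-blanker
    and scan-generator timing); and a greedy diffusion-controlled sampling
    (DCS) designer that produces damage-free scan masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
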