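Package: angioquant
Title: Ensemble Quantification of Angiogenic Sprouting in Microfluidic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated quantification of three-dimensional angiogenic growth
    from multi-channel confocal stacks of microfluidic gel-cage devices.
    Provides a synthetic phantom generator with analytic ground truth,
    image standardization (median filtering, normalization, Gaussian
    background elimination), gel/PDMS boundary detection by
    histogram-separation optimization, cubic-spline monolayer fitting,
    signal-weighted integral, first-moment and aspect-ratio metrics of
    sprout invasion, a finite-difference advection-diffusion solver for
    chemoattractant transport in the device, and ensemble statistics:
    condition aggregation, t-tests against basal controls, mean-standard
    deviation scaling analysis, gamma-process response simulation and
    optimal region-per-device allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    grDevices,
    graphics,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
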