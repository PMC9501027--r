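Package: dynpatlak
Title: Dynamic Whole-Body FDG PET Simulation and Patlak Parametric Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and kinetic analysis of dynamic whole-body [18F]FDG
    PET studies. Generates plasma input functions, irreversible two-tissue
    compartment tissue curves, frame-sampled time-activity curves, 4D digital
    phantoms and synthetic lesion cohorts; estimates an image-derived input
    function from an aortic tube of interest with blood-to-plasma conversion,
    double-exponential tail modelling and integral-preserving early
    interpolation; fits the Patlak graphical model (net influx rate Ki and
    apparent distribution volume Vd) per curve and voxelwise by weighted
    multilinear regression; measures SUV, Ki and Vd in spherical volumes of
    interest with liver-normalised lesion-to-background ratios; and runs
    normality-gated group comparisons, ROC analysis with the Youden cutoff
    and Spearman correlation on lesion cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
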