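Package: stedopt
Title: Online Multi-Objective Optimization of Microscope Acquisition Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online optimization of fluorescence nanoscopy acquisition
    parameters with kernelized Thompson sampling over a discretized
    parameter grid. Provides image-derived objective functions used in
    STED microscopy (signal-to-noise ratio, photobleaching,
    autocorrelation amplitude of periodic structures, Fourier ring
    correlation resolution, calcium-uncaging response statistics),
    a multi-objective optimization loop with preference articulation,
    offline baselines (grid search, random sampling, NSGA-II), a
    synthetic microscope simulator with a replay-experiment harness,
    a learned preference-ranking model, a fully convolutional image
    quality rater, and regret/bootstrap evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
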