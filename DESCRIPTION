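Package: axonmap
Title: Semi-Automatic 3D Axon Tracing and Synaptic Population Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of long-range axonal projections and synaptic
    populations from light microscopy and patch-clamp data. Implements a
    two-stage semi-automatic axon tracer for calibrated 3D confocal stacks
    (distance-transform seed generation followed by Hessian-eigenvector
    vectorial tracking with medial-axis correction) and axonal density
    measurement in um per um^3; sum-of-Gaussians decomposition of all-point
    histograms (Freedman-Diaconis binning, chi-square guided model selection,
    component area fractions and size-class cutoffs) for synapse-size and
    quantal-amplitude distributions; passive membrane and miniature EPSC
    feature extraction (peak amplitude, 10-90% rise time, amplitude-weighted
    bi-exponential decay, event-frequency regression); and ground-truthed
    synthetic data generators (tubular image phantoms, Gaussian-mixture
    samples, synaptic current traces) for validation. Includes a command-line
    interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
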