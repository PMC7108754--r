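Package: insfoct
Title: Label-Free Functional OCT Analysis of Infrared Neural Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-locked functional optical
    coherence tomography (fOCT) of infrared neural stimulation (INS),
    with co-registered intrinsic optical signal imaging (OISI) and
    extracellular electrophysiology. Implements prestimulus baseline
    statistics, an adaptive run-length significance detector for
    B-M-mode intensity series, speckle-decorrelation angiography with
    avascular masking and a blood-flow velocity index, fractional
    scattering-change (dR/R) aggregation with negative-response
    inversion, depth-resolved and region-of-interest time courses,
    onset/peak latency estimation, radiant-exposure dose-response
    regression, translation-search image coregistration, peristimulus
    time histograms and paired response tests. A synthetic-data module
    generates B-M OCT series with multiplicative speckle, vessels and
    programmed activation, OISI frame series, flow-phantom series and
    Poisson spike trains with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
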