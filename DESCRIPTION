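Package: rttmatch
Title: Retention Time Trajectory Matching for Targeted Chromatographic
    Peak Identification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mass-spectrometry-free identification of chromatographic peaks
    in targeted analysis.  Retention times of the peaks detected in a sample
    chromatogram are compared, as one global trajectory, against a library of
    pre-characterized retention time trajectories.  Candidate peak-to-compound
    assignments are enumerated under injectivity, elution-order preservation
    and a retention-time cutoff window, screened with internal-standard
    residuals, and ranked by mean squared residual; peaks belonging to no
    target compound are flagged as interferents.  The library can be expanded
    by linear hybridization of measured trajectories to tolerate retention
    time drifts outside the measured envelope.  Includes a synthetic
    chromatogram-family generator with known ground truth, a local-maximum
    peak apex detector, and a command line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
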