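Package: polarmm
Title: Mueller-Matrix Polarimetry Analysis of Fibrous Tissue Injury and Recovery
Version: 0.1.0
Authors@R:
    person("polarmm", "developers", email = "polarmm@example.org", role = c("aut", "cre"))
Description: Tools for quantitative Mueller-matrix polarimetry of fibrous
    tissue such as tendon. Provides the per-pixel Mueller image container with
    reconstruction from polarization-state-generator/analyzer measurements,
    Lu-Chipman polar decomposition and Mueller-matrix transformation (MMT)
    parameter maps, rotation-variance-aware first-order statistics and
    frequency distribution histograms, a Fisher-type learned polarization
    feature parameter (PFP) with treatment scoring, virtual polarization
    staining, and a synthetic phantom generator with known ground truth for
    end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    MASS
Config/testthat/edition: 3
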