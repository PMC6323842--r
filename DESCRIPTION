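Package: dose4d
Title: Simulation of 4DCT Dose-Accumulation Uncertainty Under Heterogeneous
    Respiratory Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying how irregular (heterogeneous)
    respiratory motion makes the traditional ten-phase 4DCT accumulated dose
    diverge from the true accumulated dose in lung stereotactic body
    radiotherapy. Provides a per-cycle cos^4 breathing-motion generator with
    Gaussian-distributed amplitude and period, phase-based cycle sampling,
    a voxelized digital lung-tumour phantom with spherical targets, a
    parametric plan-dose surrogate with configurable isodose level and
    penumbra, rigid 4D dose accumulation with DVH (Dx) evaluation, worst-case
    dose-discrepancy statistics with parameter sweeps, and a probability-
    density-based robust internal-target-volume planning strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
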