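Package: psqanet
Title: Balanced Multimodal Prediction of Gamma Passing Rates and Dose
    Differences for Patient-Specific Radiotherapy QA
Version: 0.1.0
Authors@R:
    person("PSQA", "Maintainers", email = "psqanet@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance (PSQA) of
    intensity-modulated radiotherapy plans. Provides a synthetic PSQA data
    simulator (MLC aperture sequences, fluence rendering, plan-complexity
    metrics, a delivery perturbation model), a 2-D gamma-index engine that
    mints Gamma Passing Rate (GPR) ground truth at clinical criteria, a
    multimodal multi-task neural model that predicts GPR 3-vectors and
    dose-difference maps from a fluence image plus a 33-metric complexity
    vector, Shapley-value modality-contribution diagnostics with a dynamic
    dose-difference loss weighting rule, evaluation metrics (MAE, RMSE, R2,
    global-statistics SSIM) with GPR-interval stratified reporting, a
    multi-factor stratified splitter, and a command-line workflow
    (simulate, split, train, report, gamma).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
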