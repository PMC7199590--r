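Package: rdwards
Title: Incremental Prognostic Value of Red Cell Distribution Width in ARDS
    Mortality Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing whether red cell distribution width (RDW)
    adds prognostic value to clinical mortality models in acute respiratory
    distress syndrome (ARDS). Fits base and RDW-enhanced logistic models for
    ICU, in-hospital, and 90-day mortality; compares nested models by paired
    AUC difference (DeLong placement-value variance), category-free net
    reclassification improvement (NRI), and integrated discrimination
    improvement (IDI); classifies longitudinal RDW trajectories into
    concave, convex, uptrending, downtrending, and no-trend groups from
    per-patient quadratic fits; tests trajectory-mortality association with
    chi-square and exact contingency tests; and simulates calibrated
    synthetic ICU cohorts so the full pipeline can be exercised and
    validated without access to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
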