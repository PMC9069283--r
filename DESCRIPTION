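Package: oncotwin
Title: Digital Twin Dyad for Sequential Oropharyngeal Cancer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning and evaluating dynamic treatment regimes for
    oropharyngeal cancer with three sequential binary decisions (induction
    chemotherapy, concurrent chemotherapy versus radiotherapy alone, and neck
    dissection). Implements a finite-horizon fitted Q-learning policy trained
    backward from a composite survival/toxicity reward, a per-feature
    support-vector transition simulator acting as a patient digital twin for
    off-policy evaluation, exact backward-induction and open-loop planning
    oracles on tabular decision processes, a synthetic cohort generator
    calibrated to published marginal frequencies, and evaluation metrics
    (simulated survival and dysphagia rates with bootstrap confidence
    intervals, physician similarity, prescription-rate deltas, and a
    guideline-compliance audit).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
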