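Package: binderCEA
Title: Cost-Effectiveness of Phosphate Binders in Predialysis Chronic
    Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-state Markov cohort model (predialysis CKD, dialysis,
    dead) comparing sevelamer with calcium carbonate for hyperphosphatemia
    in predialysis chronic kidney disease, from the Malaysian Ministry of
    Health perspective. Provides a synthetic two-arm trial generator with
    competing time-to-death and time-to-dialysis endpoints, parametric
    survival fitting and lifetime extrapolation, cause-specific
    rate-to-probability conversion, discounted cost/QALY valuation,
    incremental cost-effectiveness ratios classified against WHO
    GDP-per-capita thresholds, deterministic scenario analyses, and a
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Runs are driven by a YAML configuration whose
    defaults encode the published base case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    flexsurv,
    yaml,
    jsonlite,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
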