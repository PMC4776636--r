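Package: dvhpoints
Title: Dose/Volume-Point Extraction and Cohort Statistics for Radiotherapy Plan Review
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses dose/volume-point expressions written in a standard plain-text
    syntax (e.g. D(Gy)40(cc), V(%)20(Gy), Dmax, Dmean/Rx), evaluates them against
    cumulative dose-volume histograms exported as CSV, and batch-produces
    per-structure spreadsheet reports with cohort quantile statistics for
    clinical-trial radiotherapy plan-quality review. Includes a synthetic DVH
    generator with closed-form ground truths for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'batch.R'
    'dvh-io.R'
    'evaluator.R'
    'expression.R'
    'stats-report.R'
    'synthetic.R'
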