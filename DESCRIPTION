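Package: pwideval
Title: Evaluating Identification of People Who Inject Drugs from Discharge Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation framework for electronic-health-record phenotyping of
    people who inject drugs (PWID) from hospital discharge summaries. Provides a
    synthetic admission-cohort generator that emulates the statistical structure
    of an Australian infectious-diseases inpatient cohort (prevalences,
    demographics, note length, ICD coding behaviour and classifier error rates),
    rule-based de-identification with placeholder tokens, ICD-10-AM code-group
    proxy rules for injecting drug use, a pluggable prediction interface with a
    deterministic keyword/negation reference classifier, multi-label diagnostic
    metrics with percentile bootstrap confidence intervals, prevalence-weighted
    average-F1 model comparison, and subgroup fairness auditing (parity ratios
    under the 80 percent rule, Matthews correlation coefficient).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
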