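Package: surgsafe
Title: Incident Statistics and Economic Evaluation for an AI Surgical-Safety System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a before/after implementation study of an
    AI-based surgical-safety (patient, laterality and intraocular-lens
    authentication) system. Provides exact (Clopper-Pearson) and Wilson score
    binomial confidence intervals, Woolf logit odds-ratio intervals and a
    self-contained two-sided Fisher exact test for incident counts; a
    synthetic two-period surgical case-log generator built on the five-outcome
    authentication taxonomy (not performed, successful, near miss, error,
    authentication failure); and a five-year cost-benefit / cost-effectiveness
    model with discounting, an ICER scenario grid over near-miss progression
    probabilities, one-way (tornado) sensitivity analysis and seeded Monte
    Carlo probabilistic sensitivity analysis. A pipeline driver reproduces the
    full incident and economic report either from printed study counts or from
    a simulated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
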