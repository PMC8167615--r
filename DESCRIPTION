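Package: chronicare
Title: Pathway-Driven Chronic Disease Management Engine and Retrospective
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based care-pathway engine for out-of-hospital management
    of hypertension, type 2 diabetes, COPD, and the hypertension-with-diabetes
    combination: declarative condition-action rules evaluated to fixpoint over
    patient facts, hierarchical patient stratification, follow-up scheduling,
    abnormal-condition warning detection, compliance tracking, and
    multimorbidity plan merging.  Includes a longitudinal cohort simulator
    with configurable confounding and known ground-truth treatment effects,
    and retrospective evaluation procedures: windowed before/after comparison
    with paired t-tests, causal-episode extraction, propensity-score matching
    and stratification estimators of the average treatment effect with
    refutation checks, and care-provider work-efficiency metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
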