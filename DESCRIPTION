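Package: spirointerp
Title: Rule-Based Spirometry Interpretation and Rater-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic rule engine that classifies spirometry records
    into the four conventional functional patterns (normal, obstructive,
    spirometric restriction, mixed), grades severity of airflow limitation,
    and evaluates bronchodilator reversibility from pre- and
    post-bronchodilator forced volumes, following SEPAR/ATS-ERS fixed-ratio
    criteria. Companion statistics for validating such a classifier against
    expert raters: diagnostic accuracy of the dichotomised (normal/impaired)
    call with exact Clopper-Pearson, Mercaldo logit and log-method
    confidence intervals; Cohen's kappa with asymptotic standard errors,
    category merging, severity pooling, Landis-Koch interpretation and
    intra-rater reliability; and a synthetic cohort generator that samples
    records from prescribed pattern-prevalence and severity mixes for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
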