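Package: trdhru
Title: Treatment-Resistant Depression Phenotyping and Healthcare Resource
    Utilization Analysis for Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for registry-based study of treatment-resistant depression
    (TRD): prescription-sequence phenotyping of treatment resistance at the
    second antidepressant treatment shift, construction of first-time major
    depressive disorder cohorts with diagnosis-based in-/exclusion rules,
    1:2 exact matching with index-date assignment for controls, aggregation
    of healthcare resource utilization (HRU) counts and costs over pre- and
    post-index windows, and a two-part statistical model (modified Poisson
    relative risk for any use; log-scale linear model for the amount among
    users). Includes a seeded synthetic-registry generator with latent
    treatment resistance and exported ground truth for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
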