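Package: prevproj
Title: Projecting Risk-Factor Prevalences by Multiple Imputation of Future Survey Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects population-level prevalences of binary risk factors
    (obesity, smoking, hypertension and similar indicators) from repeated
    cross-sectional health-survey data. Future survey waves are treated as
    missing data: pseudo-samples whose age and sex composition matches an
    official population forecast are appended to the observed waves, all
    missing values are simulated with chained-equations multiple imputation
    (fully conditional specification), and per-imputation prevalences are
    combined with Rubin's rules to give projections with confidence
    intervals. Includes restricted cubic spline terms for calendar time,
    BIC-based forward selection of imputation models, convergence and
    correlation-structure diagnostics, hold-out validation against an
    observed wave, and a synthetic-data generator that emulates the
    structure of five Finnish health examination surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    tools,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
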