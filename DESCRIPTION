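Package: odtcea
Title: Cost-Effectiveness Modelling of Oral Antipsychotic Formulations in
    Schizophrenia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing orally
    disintegrating (ODT) and standard oral tablet (SOT) formulations of
    olanzapine, risperidone and aripiprazole for the one-year management of
    schizophrenia from the Moroccan payer perspective (2022 MAD). Ships the
    published Moroccan input tables as fixtures and provides an
    adherence-stratified relapse outcome engine with a calibrated cycle
    exponent, resource-based costing, an expected-value evaluator and a
    patient-level Monte Carlo twin, incremental cost-effectiveness analysis
    (ICERs, dominance, net monetary benefit, efficiency frontier), one-way
    sensitivity analysis with sequential-bifurcation screening and tornado
    output, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a synthetic parameter-set generator with known
    ground truth for pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
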