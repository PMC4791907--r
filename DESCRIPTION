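Package: cmdcasefind
Title: Case-Finding Algorithms for Anxiety and Depression in Primary Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying cases of the common mental disorders (CMD)
    anxiety and depression from routinely collected, Read-coded primary care
    records, and for validating such case definitions against a survey-based
    gold standard. Implements twelve boolean case-finding algorithms over
    current and historical diagnosis, symptom and treatment codes in a
    one-year window centred on a survey response date; MHI-5 (five-item
    Mental Health Inventory) scoring with person-mean imputation and a
    configurable case cut-point; annual incidence of recorded episodes per
    1000 person-years at risk with a six-month post-registration exclusion
    and a one-year lookback; period prevalence in a continuously registered
    population; sensitivity, specificity and positive predictive value
    against the survey gold standard with characterisation of misclassified
    respondents; and a synthetic electronic-health-record generator with
    known latent CMD status so the whole pipeline is testable without access
    to identifiable patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
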