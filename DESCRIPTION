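Package: ntcpselect
Title: Model-Based Selection of Head and Neck Cancer Patients for Proton
    Therapy Using NTCP Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision engine for normal tissue complication probability
    (NTCP) model-based selection of head and neck cancer patients for
    proton therapy, following the Dutch national indication protocol.
    Ships the three revised logistic NTCP models for moderate-to-severe
    xerostomia, grade II-IV dysphagia, and tube feeding dependence at six
    months after radiotherapy; implements the delta-NTCP threshold
    flowchart (eligibility gate, delta-NTCP_max pre-screen, plan-pair
    qualification with single and same-grade summed rules); provides an
    external-validation and closed-testing model-updating toolkit
    (discrimination, calibration, intercept update, recalibration,
    revision); and generates synthetic referral cohorts with correlated
    organ-at-risk doses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
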