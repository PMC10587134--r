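Package: rtcit
Title: Reaction-Time Concealed Information Test Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing reaction-time Concealed
    Information Test (RT-CIT) experiments run under the multiple probes
    protocol. Provides a trial-level synthetic cohort generator, the
    preregistered trial- and participant-level exclusion rules, per-participant
    effect scoring (RT-CIT effect and dCIT), default (JZS) Bayes factors for
    one- and two-sample contrasts with a sequential Bayes-factor sampling
    plan, and a detection-efficiency analysis based on a simulated naive null,
    bootstrapped ROC AUCs, and the Hanley-McNeil comparison of two AUCs. A
    seeded end-to-end pipeline reconstructs cohort summary tables and the
    batch-wise evidential flow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
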