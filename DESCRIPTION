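Package: breath2plasma
Title: Breath-to-Plasma Propofol Pharmacokinetics and Agreement Analysis
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking exhaled propofol concentrations measured by
    online mass spectrometry to plasma concentrations in small-animal
    studies. Provides quadratic signal-to-concentration calibration with
    limit-of-detection bookkeeping, closed-form one/two/three-compartment
    bolus and infusion models with least-squares fitting and AIC model
    selection, censoring and breath-plasma pairing rules, log-log
    regression with breath-based plasma prediction, agreement statistics
    (intraclass correlation, Bland-Altman limits of agreement), group
    comparisons, a synthetic cohort generator emulating a three-group
    rat bolus design, and a reproducible command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
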