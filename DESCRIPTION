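Package: seamsel
Title: Seamless Phase II/III Trial Designs with Treatment Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-stage seamless phase II/III clinical
    trials that compare K experimental treatments with a common control,
    select the best-performing treatment at an interim analysis subject to a
    futility rule, and test its null hypothesis using data from both stages.
    Implements six final decision rules (the conventional stage-2-only test,
    the Thall-Simon-Ellenberg weighted pooled z-test, and closed testing
    procedures combining stage-wise p-values by inverse chi-square or inverse
    normal rules with Simes or Dunnett intersection tests), Bayes-optimal and
    pseudo-optimal likelihood-ratio decision rules for families of treatment
    effect configurations, Monte Carlo calibration of critical values to a
    familywise error rate, and tools for power estimation, relative
    efficiency, optimal division of a fixed total sample size between stages,
    and the value of stage-1 data in the final analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
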