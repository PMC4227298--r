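Package: pilotsize
Title: Sample Size Requirements for External Pilot Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and closed-form machinery for deciding how large an
    external pilot randomised controlled trial must be to estimate a
    continuous outcome's standard deviation or a binary event rate with
    useful precision. Implements the sampling distribution of the pooled
    standard deviation with chi-square confidence limits, Wilson score
    intervals with exact binomial enumeration, relative precision gain per
    added subjects, bias assessment, normal-approximation power and sample
    size for two-arm superiority trials, confidence-based inflation of
    variance estimates, and assurance (the probability that a trial planned
    from a pilot estimate attains a stated power floor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
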