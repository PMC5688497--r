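Package: birthrisk
Title: Birth Risk Distributions, Contraceptive Prevalence and Method-Mix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ecologic analysis of the distribution of births across
    demographic risk categories (parity, preceding birth interval, and
    mother's age at birth) as a function of modern contraceptive prevalence
    (mCPR) and contraceptive method-mix. Classifies individual birth
    histories into risk categories, aggregates them to survey-level
    summaries (category percentages, mCPR, method-mix shares, period total
    fertility rate), fits per-category log-linear regressions including a
    country random-intercept model estimated by restricted maximum
    likelihood with empirical-Bayes country effects, and projects
    renormalized birth-risk distributions under method-specific
    contraceptive scale-up scenarios. Includes a seeded synthetic-data
    generator for survey panels and individual birth histories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
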