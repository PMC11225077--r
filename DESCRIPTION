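Package: polypillcea
Title: Markov Cohort Cost-Utility Model of a Cardiovascular Polypill
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lifetime Markov cohort cost-utility model comparing a
    four-component cardiovascular polypill with its individual components
    given as monotherapy for primary prevention in adults aged 35 and over.
    Provides method-of-moments distribution fitting for uncertain inputs,
    a nine-state cohort engine with age-specific background mortality and
    standardized mortality ratios, incremental cost-effectiveness analysis
    with dominance classification, one-way tornado sensitivity analysis,
    Monte-Carlo probabilistic sensitivity analysis, and cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
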