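Package: mstagecea
Title: Cost-Effectiveness of Adding Liver MRI to CT for Metastasis
    Staging of Pancreatic Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic model comparing two imaging strategies for
    initial distant-metastasis (M-) staging of pancreatic cancer:
    contrast-enhanced CT alone versus CT plus additional contrast-enhanced
    liver MRI. A diagnostic decision tree feeds a five-state annual-cycle
    Markov cohort model with discounted costs and quality-adjusted life
    years. Provides incremental cost-effectiveness ratios, net monetary
    benefit, deterministic (tornado and threshold) and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves, a
    structural-assumption search against published base-case results, and
    an individual-level microsimulation used as an independent oracle for
    the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
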