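Package: mbcmarkov
Title: Markov Cohort Cost-Effectiveness Model for Third-Line HER2+ Metastatic
    Breast Cancer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-state, half-cycle-corrected Markov cohort model comparing
    neratinib plus capecitabine against lapatinib plus capecitabine as
    third-line therapy for HER2-positive metastatic breast cancer, from a
    payer perspective over a five-year horizon. Per-cycle transition
    probabilities are derived from median survival summaries (overall
    survival, progression-free survival, duration of response) by the DEALE
    declining-exponential method; discounted costs and quality-adjusted
    life-years feed incremental cost-effectiveness ratios and net monetary
    benefit with a GDP-tiered decision rule. Includes one-way deterministic
    sensitivity analysis (tornado), second-order Monte-Carlo probabilistic
    sensitivity analysis with method-of-moments beta/gamma parameter
    distributions, cost-effectiveness acceptability curves, a synthetic
    scenario generator for property testing, and YAML/CSV/JSON import and
    export of all model inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
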