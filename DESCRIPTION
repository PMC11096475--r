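Package: cqsmeta
Title: Stratified Meta-Analysis Comparing CQS-2B and RoB 2 Trial Appraisal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores controlled clinical trials with the four-criterion
    Composite Quality Score (CQS-2B), stratifies trial-level effect data by
    CQS corroboration level and by overall Cochrane Risk of Bias 2 (RoB 2)
    rating, pools effect estimates in two stages with DerSimonian-Laird
    random-effects meta-analysis (Mantel-Haenszel pooling for dichotomous
    data), compares the two appraisal tools' pooled estimates with a Wald
    test, and maps results to the qualitative clinical conclusions each tool
    licenses. Includes a synthetic trial-corpus generator with configurable
    meta-epidemiological bias mechanisms (lack of allocation concealment,
    lack of double blinding, small per-arm sample size) and a recovery
    routine that estimates those biases back from pooled strata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
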