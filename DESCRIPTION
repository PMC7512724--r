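Package: bnpool
Title: Linear Opinion Pooling for Expert-Elicited Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining probability assessments from panels of experts
    in discrete Bayesian networks. Implements Prior Linear Pooling (average the
    experts' conditional probability tables entry-wise, then propagate a single
    pooled network) and Posterior Linear Pooling (propagate one network per
    expert, then pool the marginal distributions at nodes of interest), together
    with exact inference by variable elimination, a brute-force enumeration
    oracle, covariate-based subgroup analysis, diagnostic-scenario delta tables,
    across-expert descriptive summaries, seeded synthetic expert-panel
    generators, and readers/writers for BIF, XMLBIF and a panel JSON schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
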