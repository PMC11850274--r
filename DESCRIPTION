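Package: stylegauge
Title: Microblog-Based Assessment of Parenting Style
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the parenting style experienced by microblog
    users from their public post histories. Implements s-EMBU-C questionnaire
    scoring with validity filtering and rule-based style typing
    (positive/mixed/negative), lexicon-category word-proportion analytics with
    group comparisons, a deterministic offline text-embedding fallback, a
    recurrent attention-pooling regression model with a correlation-injection
    layer predicting the three parenting dimensions (Rejection, Emotional
    Warmth, Overprotection), training/evaluation utilities with classic
    baselines and an ablation driver, and a synthetic corpus generator that
    plants style-dependent lexical signal so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    glmnet,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
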