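Package: irgpair
Title: Immune-Related Gene-Pair Prognostic Signatures for Survival Risk
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rank-based immune-related gene-pair (IRGP) prognostic
    signatures from tumor expression and survival data. Provides
    differential-expression screening, within-sample gene-pair binarization
    with a prevalence filter, self-contained survival statistics
    (Kaplan-Meier, log-rank, Cox proportional hazards with Efron ties, and
    an L1-penalized Cox path with cross-validated lambda selection via
    cyclic coordinate descent), risk-score stratification with a
    time-dependent ROC cutoff, multivariate independence testing against
    clinical covariates, MAF mutation summaries, and a synthetic survival
    cohort generator with a recorded truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    withr
Config/testthat/edition: 3
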