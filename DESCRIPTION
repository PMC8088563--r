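Package: nestedpower
Title: Power Analysis for Differential Expression in Hierarchical
    Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell RNA-seq expression data with the nested
    (cells-within-individual) correlation structure of real multi-subject
    experiments and uses those simulations to estimate statistical power and
    type-1 error for tests of differential expression. A generative model
    (gamma-distributed gene means, a linear mean-variance trend for
    inter-individual variation, a logarithmic mean-dispersion trend for
    within-individual negative-binomial counts, and a bounded-gamma dropout
    process) is estimated from pilot data or supplied as defaults. Power is
    computed by Monte Carlo for a two-part hurdle model with a per-individual
    random intercept, alongside a naive cells-as-independent hurdle and a
    pseudo-bulk comparator, for binary group designs and continuous
    phenotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
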