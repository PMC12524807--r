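Package: coxformer
Title: Transformer-Based Deep Survival Modelling for High-Dimensional Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a transformer encoder survival model on high-dimensional bulk
    gene-expression profiles. Expression vectors are layer-normalized, linearly
    embedded into a short token sequence with a learnable CLS token, passed
    through multi-head self-attention encoder blocks, and reduced to a scalar
    Prognosis Index trained by minimizing the Cox negative log partial
    likelihood with Adam and weight decay. Includes a linear Cox baseline
    trained under the same objective, concordance evaluation with explicit
    tie policies, a repeated k-fold cross-validation and grid-search harness,
    sampling-based Shapley gene attribution, and a Weibull
    proportional-hazards cohort simulator with controlled censoring so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
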