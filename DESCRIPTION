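Package: mpanis
Title: Non-Indigenous Species Pressure and Coastal Marine Protection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of non-indigenous mollusc species (NIS)
    prevalence along protected and unprotected coasts. Implements
    length-weighted coastal protection scoring, an aquaculture invasion-vector
    index, Simpson and Margalef diversity summaries, Pearson correlation
    screening with Bonferroni and permutation tests, correlation-matrix
    principal component analysis with bootstrap eigenvalue intervals,
    gap-rule outlier screening, multiple linear regression with an overall
    ANOVA F test, normal-family bivariate GLMs with deviance G tests,
    Durbin-Watson and Breusch-Pagan diagnostics, regional subset re-analysis,
    and a synthetic two-region site generator for end-to-end validation.
    Ships a 30-site reference dataset from a two-island Pacific survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
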