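Package: kerneltransfer
Title: Transfer Learning for Kernel Regression via Projection and Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adapting a kernel regression model trained on a source
    task to a related target task. Implements minimum-norm and ridge kernel
    regression with the Laplace kernel and the neural tangent kernel of a
    fully-connected ReLU network, and three transfer operators over a frozen
    source model: projection (a secondary model fit on source predictions),
    translation (an additive correction fit on residuals), and their
    combination. Includes exact closed-form risk formulas for the three
    estimators in the over-parameterized linear setting together with a
    Monte-Carlo risk oracle, logarithmic learning-curve (scaling-law) fitting
    and extrapolation, regression metrics used in virtual drug screening, and
    synthetic generators for linear transfer tasks, clustered classification
    transfer, and drug-by-cell-line expression screens.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
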