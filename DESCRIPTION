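Package: tqreg
Title: Regularized Quantile Regression with Tensor Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear quantile regression for a scalar response with scalar
    covariates and a tensor-valued covariate whose effect carries a low-rank
    Tucker decomposition. The non-differentiable check loss is smoothed by a
    generalized Huber function with a vanishing smoothing parameter, and the
    model is estimated by cyclic block relaxation with Barzilai-Borwein
    gradient steps. Penalties (lasso, fused lasso over a spatial adjacency
    graph) act on the composed tensor effect rather than on the decomposition
    components, which keeps coefficient maps interpretable. Includes rank
    selection by BIC, penalty tuning by cross-validation, and a seeded
    simulation suite with binary two-dimensional signal tensors and
    heavy-tailed error families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
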