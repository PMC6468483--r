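Package: latentpls
Title: Projection to Latent Structures Regression for Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for projection to latent structures (PLS2) regression as
    used in metabolomics: the eigenvalue-form PLS2 algorithm with iterative
    deflation, post-transformation into predictive and orthogonal latent
    subspaces (ptPLS2), orthogonally-constrained PLS2 (oCPLS2) for
    design-driven nuisance removal, kernel PLS2 for non-linear problems,
    model interpretation (VIP, selectivity ratio, correlation loadings,
    w*q coordinates), validation (cross-validated Q2, permutation tests,
    component selection, SDEC/SDEP, stratified splitting), PLS2-DA
    classification with Cohen's kappa, variable selection (Monte-Carlo
    stability selection, UVE-PLS), data pre-treatment (PQN normalization,
    transforms, scaling, imputation), and seeded synthetic-data generators
    with planted latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, MASS, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
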