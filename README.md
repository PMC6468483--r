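# latentpls

Projection to latent structures (PLS2) regression for metabolomics, with the
modern toolchain built around it: post-transformation into predictive and
orthogonal latent subspaces (ptPLS2), orthogonally-constrained PLS2 (oCPLS2)
for design-driven nuisance removal, kernel PLS2 for non-linear problems, and
a full interpretation / validation / variable-selection layer.

Metabolomic data matrices are short and wide, collinear and redundant:
hundreds or thousands of correlated features measured on a few dozen
samples. PLS2 handles this by regressing the response block on a small set
of orthogonal latent variables,

    X = T Pᵗ + E_A,   Y = T Qᵗ + F_A,   T = X W*,   B = W* Qᵗ,

where each weight vector solves the eigenvalue problem
`Eᵗ F Fᵗ E w = λ w` on the current residual blocks and both blocks are
deflated by the score projector after every extraction. The package
implements this eigenvalue form and everything a practitioner layers on top
of it:

| area | functions |
|---|---|
| core fit | `pls2()`, `predict()`, `coef()`, `explained_variance()` |
| structured noise | `post_transform()`, `transform_weights()`, `predictive_vip()` |
| design constraints | `ocpls2()`, `constraint_matrix()` |
| non-linearity | `kpls2()`, `kernel_spec()`, `gram_matrix()` |
| interpretation | `vip()`, `selectivity_ratio()`, `correlation_loadings()`, `wq_coordinates()` |
| validation | `cv_q2()`, `permutation_test()`, `select_ncomp()`, `error_metrics()`, `stratified_split()` |
| classification | `plsda()`, `cohens_kappa()`, `kappa_cv()`, `select_ncomp_da()` |
| variable selection | `stability_selection()`, `vip_filter()`, `uve_pls()` |
| pre-treatment | `pre_treat()`, `pqn_normalize()`, `scale_columns()`, `impute_missing()` |
| simulation | `sim_latent_data()`, `sim_paired_data()` |
| workflows | `run_workflow()`, `write_model()`, `read_model()` |

## Worked example

A paired design: a quantitative response drives one latent direction while a
paired two-level factor (coded 0/1 in `Z`) shifts an overlapping set of
variables — structured noise that confounds a plain PLS2 fit. The
constrained model removes it by forcing every score orthogonal to `Z`:

```r
library(latentpls)

d   <- sim_paired_data(N = 40, P = 50, seed = 13)
fit <- ocpls2(d$X, d$Y, d$Z, ncomp = 2)
fit
#> Orthogonally-constrained PLS2 model: 50 predictors, 1 response(s), 2 latent variable(s)
#> R2 per response: y1 = 0.988
#> max |Z' T| = 2.93e-14

post_transform(fit)
#> Post-transformed PLS2 model: 1 predictive + 1 orthogonal latent variable(s)
#> R2 per response: y1 = 0.988

cv_q2(fit, k = 7, seed = 1)$q2
#> 0.965

permutation_test(fit, n_perm = 99, seed = 1)
#> Permutation test (99 permutations)
#>   R2: observed = 0.9877, p = 0.01
#>   Q2: observed = 0.9654, p = 0.01
```

The fit explains the response (R² = 0.988) while its scores are orthogonal
to the nuisance factor to machine precision; seven-fold cross-validation
confirms predictive power (Q² = 0.965), and 99 response permutations never
reach the observed statistics (p = 1/100, the smallest attainable value).
Post-transformation splits the two latent variables into one predictive and
one orthogonal component, after which `selectivity_ratio()` ranks variables
against an F-based threshold and `predictive_vip()` separates
response-related from structured-noise variables.

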