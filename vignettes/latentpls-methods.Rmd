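---
title: "PLS2 modelling for metabolomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS2 modelling for metabolomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentpls)
```

## The model

Metabolomic tables are short and wide, strongly collinear and noisy, which
rules out ordinary least squares. Projection to latent structures (PLS2)
regresses a response block $Y \in \mathbb{R}^{N \times M}$ on a predictor
block $X \in \mathbb{R}^{N \times P}$ (both mean-centred, optionally scaled)
through a small set of orthogonal latent variables:

$$X = T P^t + E_A, \qquad Y = T Q^t + F_A, \qquad T = X W^*,$$

with regression coefficients $B = W^* Q^t$ and $W^* = W (P^t W)^{-1}$.
`pls2()` implements the eigenvalue form of the algorithm: at step $i$ the
weight $w_i$ is the dominant eigenvector of
$E_{i-1}^t F_{i-1} F_{i-1}^t E_{i-1}$, the score is $t_i = E_{i-1} w_i$, and
both residual blocks are deflated by
$I - t_i (t_i^t t_i)^{-1} t_i^t$. This solves, per component, the
maximization of the covariance $t_i^t u_i$ between X- and Y-scores under
unit-norm weights. The construction yields mutually orthogonal scores,
orthonormal weights, and an upper-triangular $P^t W$ with determinant one —
properties the test suite asserts on every seeded fit, since the whole
interpretation layer depends on them.

Because these are matrix decompositions rather than probability models, no
distributional assumptions are made; validation is entirely resampling-based.

### Numerical choices in the core

* The dominant eigenvector is computed from the SVD of the $P \times M$
  cross-product $E^t F$ rather than the $P \times P$ operator: identical
  mathematically, cheaper and stabler for wide blocks.
* Eigenvector signs are conventional. We fix them by making the
  largest-magnitude weight entry positive; all reported quantities that are
  not sign-invariant (scores, loadings) inherit this convention, and the
  oracle comparisons in the tests align signs before differencing.
* "No remaining covariance" is declared when the leading eigenvalue falls
  below $10^{-12} \times \|X^t Y\|_F^2$ (the scale of the undeflated
  problem). The model is then truncated with a recorded warning rather than
  an error: requesting more components than the data support is routine in
  scans over component counts.
* The component cap is $\min(N-1, P)$. Non-centred input with
  `center = FALSE` is an error naming the offending block, not a silent
  re-centre.
* $u_i$ and $c_i$ are stored with $c_i^t c_i = 1$, matching the unit-norm
  constraint of the covariance maximization; they are diagnostics (the
  $t$–$u$ plot detects non-linearity) and do not enter $B$.

## Post-transformation (ptPLS2)

Structured noise — systematic variation unrelated to the response — inflates
PLS2 models with extra latent variables. Running the deflation loop with any
non-singular transform $\tilde W = W H$ of the weights leaves $B$ and both
residual blocks unchanged (`transform_weights()`; the suite verifies this for
50 random $H$ at $10^{-9}$). `post_transform()` exploits the freedom: it
takes $G$ orthogonal from the SVD of $W^t X^t Y$, so that directions with
non-zero singular values span the Y-predictive subspace
($A_p = \operatorname{rank}(Y^t X W)$, relative cutoff $10^{-10}$) and
null-space directions produce scores exactly orthogonal to $Y$:

$$X = T_p P_p^t + T_o P_o^t + E, \qquad Y = T_p Q_p^t + F.$$

Two choices here were genuinely open:

* **Extraction order.** Nothing forces orthogonal or predictive components
  first; $B$ and the residuals are invariant either way, but score plots
  differ. We extract orthogonal components first so the predictive scores
  are cleaned of structured noise, which reproduces the familiar
  OPLS-equivalent behaviour in the single-response case. This is a
  documented package choice, not a claim about the method's original intent.
* **Degenerate split.** When $A_o = 0$ there is nothing to separate and the
  parent model is returned unrotated ($G = I$), which makes the trivial
  identities ($T_p = T$, split VIP = classic VIP) exact.

The split VIP scores weight the predictive block by explained Y-variance and
the orthogonal block by explained X-variance — orthogonal components explain
zero Y-variance by construction, so an X-weighted score is the only
informative choice. Both score vectors keep the mean-square-one property.

## Orthogonally-constrained PLS2 (oCPLS2)

When nuisance factors are part of a designed experiment (e.g. paired
sampling), `ocpls2()` codes them in a constraint matrix $Z$ and projects the
covariance operator onto the complement of the right singular vectors of
$Z^t E_{i-1}$ before each weight extraction, so every score satisfies
$Z^t T = 0$. Details that the method statement leaves open:

* $V_i$ is recomputed at every deflation step, as the step index in the
  projected eigenproblem requires.
* The numerical rank of $Z^t E_{i-1}$ uses a relative cutoff of $10^{-10}$,
  floored at round-off scale ($\varepsilon \cdot \max(L, P) \cdot
  \|Z\|_F \|E\|_F$) so that a constraint orthogonal to the data selects no
  direction and the fit reduces exactly to unconstrained PLS2.
* $Z$ is not centred automatically: a two-level factor coded 0/1 is the
  common convention, and `constraint_matrix()` offers centred coding for
  unbalanced designs as an explicit option (default raw).

Note that constraining against a response-independent factor is not free in
finite samples: the dummy retains chance correlation with noise, so $B$
shifts at noise level even when the nuisance effect is exactly zero. The
tests therefore assert exact equality only for $Z^t X = 0$ and closeness of
$R^2$ otherwise.

Post-transformation composes with constrained fits: the transformed scores
span the same space as the originals, so $Z^t T = 0$ survives the rotation.

## Kernel PLS2

`kpls2()` performs the same extraction in a feature space reached through a
kernel (linear, polynomial, RBF; default RBF width $\gamma = 1/P$). The
training Gram matrix is double-centred; at each step the score is the image
of the dominant eigenvector of the $M \times M$ matrix $F^t K F$ under the
residual kernel, which coincides with the primal eigenvalue step when the
kernel is linear. That linear-kernel equivalence — predictions and
cross-validated $Q^2$ identical to `pls2()` at $10^{-7}$ — is the
correctness anchor for the dual algebra, and an explicit degree-2
feature-map oracle verifies that test kernels are centred with training
statistics only (no test-set leakage). Kernel models support prediction and
score inspection; per-variable importance is deliberately not offered, since
feature-space weights do not map back to single metabolites.

## Interpretation layer

* **VIP**: $\mathrm{VIP}_i = \sqrt{P \sum_j W_{ij}^2\,SSY_j / SSY}$ with
  $SSY_j = \|t_j\|^2 \|q_j\|^2$. The estimator for $SSY_j$ is the standard
  reconstruction sum of squares; with orthonormal weight columns it makes
  $\overline{\mathrm{VIP}^2} = 1$ exact, which the suite asserts at
  $10^{-8}$ on every fit.
* **Selectivity ratio**: per variable, explained variance from
  $T_p P_p^t$ over unexplained variance from $T_o P_o^t + E$; defined only
  for $A_p = 1$ (an explicit error otherwise — no silent reduction of
  multi-response models). The selection threshold is the upper F-quantile
  with $(N-2, N-3)$ degrees of freedom, the convention that reproduces the
  published worked value $F_{(0.05,36,35)} = 1.75$ at $N = 38$. A variable
  with zero predictive variance gets SR 0; one with zero residual variance
  gets $+\infty$ with a flag (the zero-numerator rule wins when both are
  zero).
* **Correlation loadings** and **w\*q coordinates** are direct Pearson
  correlations with the scores and paired $W^*$/$Q$ coordinates grounded in
  $B = W^* Q^t$; constant variables are flagged and reported as correlation
  zero, and the w\*q table warns beyond three components, where the display
  stops being readable.

## Validation

$Q^2 = 1 - PRESS/SS$ from k-fold cross-validation (default seven-fold,
seeded random partition; venetian blinds available), with pre-treatment
re-estimated inside each training fold, PRESS accumulated from out-of-fold
predictions and SS taken about the training-fold mean on the modelled
(transformed) scale. Permutation tests permute response rows jointly and
re-run the *entire* pipeline per permutation, including the CV loop for
$Q^2$; p-values carry the add-one correction, hence
$p \ge 1/(n_{perm}+1)$. Because the method statement does not pin the
permutation statistic down, both $R^2$ and $Q^2$ (or training and CV kappa
for classifiers) are reported with separate p-values.

Component selection takes the first local maximum of the response-averaged
$Q^2$ (averaging is our choice for multi-response models) subject to passing
the permutation test; exhaustion of candidates returns a failure status as
data, not an exception. SDEC/SDEP are root mean squared errors with divisor
$n$, reported in original response units — the square-root or log response
transform stored in the model is inverted before any error is computed.

`stratified_split()` bins a quantitative response into quantile strata and
fills a training set of exactly `round(N * fraction)` samples by largest
remainder, mirroring the common calibration-set construction (e.g. 38/21
from 59).

## Classification

PLS2-DA regresses an autoscaled 0/1 dummy class matrix on the predictors and
then — always — applies LDA to the scores; raw PLS2-DA predictions are never
thresholded, because class membership is not defined without the second
step. LDA priors default to training frequencies (configurable to equal).
New samples are projected as $X_{new} W^*$ under training pre-treatment.
Performance is Cohen's kappa (in calculation, by seven-fold CV, and in
prediction); with balanced classes the leading latent variables maximize
among-group variation, which the tests pin to the two-class mean-difference
direction. The model-size guard `ncomp < N - G` keeps the pooled
within-class covariance invertible.

## Variable selection

* **Stability selection**: 100 Monte-Carlo subsamples by default, read as
  independent per-sample inclusion with probability 0.70 (expected 70%
  subsample; fixed-fraction subsampling would be a config variant). Inside
  each subsample the component count and the VIP threshold (default grid
  0.8/1.0/1.2/1.5 — the inner optimization is only said to exist, not
  specified) are tuned by CV kappa or CV $Q^2$; the VIP filter is applied
  once per subsample, not iterated. Variables surviving in more than half
  the sub-models are relevant; out-of-subsample predictions give a
  percentile 95% CI for performance. Degenerate subsamples (a class lost)
  are redrawn and counted.
* **UVE-PLS**: appends $P$ artificial noise columns at $10^{-10}$ of each
  column's scale (vanishing influence on the fit), jackknifes $B$
  leave-one-out, and eliminates experimental variables whose reliability
  $|\bar b_j / s_{b_j}|$ does not exceed the maximum over artificial
  columns. The leave-one-out formulation is the classic one; it is restricted
  to single-response models, where the reliability ratio is well defined.

## Synthetic data: what it emulates and what it does not

`sim_latent_data()` draws standard-normal scores and sparse $\pm 1$ loading
patterns on disjoint variable blocks (orthonormal by construction), builds
$X = T_p P_p^t + T_o P_o^t + E$ and $Y = T_p Q_p^t + F$ with i.i.d.
Gaussian residuals, and returns the full ground truth. Orthogonal scores are
re-orthogonalized against the realized response, so the predictive/orthogonal
split is exact *in-sample* — ideal for recovery tests, but it means the
generator cannot reproduce one real-data pathology: structured noise with
chance sample correlation to the response, the regime in which variables
with high overall VIP turn out to be pure structured noise. Tests built on
this generator therefore demonstrate correct recovery of planted structure,
not robustness to every confounding pattern of real spectra. The generator
also makes no attempt at realistic peak shapes, heteroscedastic noise or
missingness patterns.

Default conditions: $N = 40$, $P = 50$, one predictive and one orthogonal
component, loading sparsity 0.2, score standard deviation (`effect_size`) 3
and residual noise 0.3 — a high signal-to-noise reference regime under which
planted structure is recoverable essentially perfectly, as a methods
demonstration should be. `sim_paired_data()` adds a paired 0/1 nuisance
factor whose scores are on the same unit-sd scale as the predictive ones and
whose loading overlaps the predictive loading with cosine 0.5: without
overlap a balanced paired factor is exactly orthogonal to the response
direction and could never confound an unconstrained fit in the first place.
The quadratic response option drives the response by the squared first score
and is what motivates the kernel path in the tests.

## Problem sizes and runtime

The suite runs at desk scale by design: fits of $20\text{–}60$ samples and
$8\text{–}200$ variables, 49–99 permutations where a permutation test is
part of a scan, 100 subsamples for the headline stability-selection run, and
exhaustive (4!) permutation enumeration where exactness is asserted. These
sizes were chosen so every statistical claim in the tests is decided by
construction or by wide margins, not because the algorithms are limited to
them; all loops are plain matrix algebra and scale to typical metabolomic
tables (tens to hundreds of samples, thousands of features).

## Known limitations

* Score post-transformation for kernel models (and kernel-specific variable
  importance) is not implemented; kernel interpretation is score-space only.
* The SR degrees of freedom $(N-2, N-3)$ follow the published worked
  example; other conventions exist in the literature.
* Stability-selection inner optimization cost grows as
  (components × thresholds × folds) per subsample; the defaults are chosen
  for tables up to a few thousand variables.
* `uve_pls()` is single-response by design.
* Unbalanced multi-class PLS2-DA maximizes a class-size-dependent criterion
  with no closed form; no optimality claim is made or tested there.
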