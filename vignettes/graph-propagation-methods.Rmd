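---
title: "PPI-aware graph propagational risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PPI-aware graph propagational risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ppirisk)
```

## The model

Plasma proteomic panels measure each protein's expression independently, but
disease-relevant signal often arises from proteins acting together through
protein–protein interactions (PPIs). This package models that synergy with a
deliberately shallow, fully explainable architecture: one closed-form graph
propagation layer followed by one logistic estimation layer per biomarker.

Let $X \in \mathbb{R}^{d \times n}$ hold bounded expression values
(*independent effects*) for $d$ proteins and $n$ participants, and let
$W \in \mathbb{R}^{d \times d}$ be a symmetric, nonnegative PPI weight matrix
with zero diagonal. With the symmetric normalized Laplacian
$L = I_d - D^{-1/2} W D^{-1/2}$ (degree $D_{ii} = \sum_k W_{ik}$; isolated
nodes contribute identity rows), the *synergetic effects*
$Z \in \mathbb{R}^{d \times n}$ minimize

$$\mathrm{tr}(Z^\top L Z) \;+\; (Z - X)^\top \Phi\, (Z - X),$$

a trade-off between **smoothness** (interacting proteins should have similar
representations) and **steadiness** (each protein should remain close to its
own measurement). $\Phi = \mathrm{diag}(\phi)$ carries one positive
*propagation intensity* per protein: small $\phi_i$ lets protein $i$ absorb
more of its neighbours' signal, large $\phi_i$ pins it to its own expression.
The minimizer is closed form,

$$Z = (\Phi + L)^{-1} \Phi X,$$

a single all-hop propagation: no layer stacking, no neighbourhood sampling.
Each biomarker $b$ then gets a linear score through its *estimation
parameters* $\theta_b \in \mathbb{R}^d$ and a logistic link,
$P_b = 1/(1 + e^{-\theta_b^\top Z})$, with no intercept. Both parameter sets
are trained jointly by full-batch gradient descent on the summed binary
cross-entropy plus a ridge penalty
$\delta(\lVert\phi\rVert^2 + \sum_b \lVert\theta_b\rVert^2)$.

The gradients are analytic. For $\theta_b$,
$\nabla\theta_b = \tfrac1n Z (P_b - Y_b) + 2\delta\theta_b$. For $\phi$ the
chain rule passes through the linear solve: with $A = \Phi + L$ and
$G = \tfrac1n \sum_b \theta_b (P_b - Y_b)^\top$, the implicit derivative
$\partial Z/\partial\phi_i = A^{-1} E_{ii} (X - Z)$ gives

$$\nabla\phi_i = \mathrm{row}_i(A^{-1} G) \cdot \mathrm{row}_i(X - Z)
  + 2\delta\phi_i.$$

One Cholesky factorization of $A$ per epoch serves both the propagation of
all $n$ sample columns and the $A^{-1}G$ solve. The test suite verifies both
gradients against central finite differences (relative error $\le 10^{-5}$
over 20 seeded instances) — that agreement, not any particular matrix
layout, is the implementation contract.

## Tunable parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `delta` | ridge weight on $\phi$, $\theta_b$ (and covariate weights) | `1e-3` | weak complexity control; never specified upstream, exposed in `gpnet_control()` |
| `eta` | learning rate | `0.001` | the setting used with ADAM in the reference experiments |
| `optimizer` | `"adam"` or `"gd"` | `"adam"` | ADAM matches the experimental setup; plain GD is kept for the descent-property checks |
| `max_epochs`, `tol` | stopping rule | `2000`, `1e-6` | relative-loss plateau; the training loop's stopping criterion is otherwise open |
| `phi_min` | positivity floor for $\phi$ | `1e-6` | $(\Phi+L)$ must stay positive definite; $\phi$ is projected after every update |
| `clip` | risk clipping bound | `1e-12` | the cross-entropy is undefined at 0/1 |
| `theta_init` | `"zeros"` or `"random"` | `"zeros"` | zero start gives the analytically known initial loss $B\ln 2$, which the tests assert |

Two conventions deserve emphasis. First, $\phi$ is unconstrained in the
original formulation, but positivity is required for the objective to be a
sensible trade-off and for $(\Phi+L)$ to be invertible; projection to
$[10^{-6}, \infty)$ preserves the plain update while guaranteeing a solvable
system. Second, the cross-entropy is implemented with its standard sign
(nonnegative, minimized at $P = Y$); the corresponding gradient is exactly
the one used by the training loop.

## The surrounding pipeline

**Preprocessing** (`filter_missing_proteins`, `impute_knn`,
`scale_expression`): proteins with more than 5% missing samples are dropped
(a protein at exactly 5% is retained — the exclusion rule is strict);
remaining gaps are filled by $k$-nearest-neighbour imputation ($k = 10$) with
neighbours found in sample space by root-mean-square distance over jointly
observed proteins, ties broken toward the lower sample index; finally each
protein row is z-scored (sample sd) and pushed through the logistic function,
bounding everything in $(0,1)$. Constant rows map to 0.5. The kNN
orientation, metric and $k$, and the sd denominator, were open choices; the
ones here are standard for proteomic panels and fully deterministic.

**Target selection** (`dea_test`, `select_targets`): per-protein Welch
two-sample t-tests compare biomarker-positive against -negative groups; a
protein is a target when its raw p-value is below 0.05 for *every*
biomarker. The moderated empirical-Bayes test used upstream is deliberately
out of scope; Welch is the documented stand-in behind the same selection
logic, and the suite checks it against `stats::t.test` and verifies null
calibration. Tests run on the scaled matrix — the matrix the model consumes.

**Network construction** (`build_network`, `network_stats`): STRING-style
edges with combined score strictly above 0.4 are kept, then the kept scores
are z-scored and logistic-rescaled into $(0,1)$ (post-threshold scoring
population; a degenerate sd yields 0.5 by convention). Density and mean
degree are reported over connected (degree $\ge 1$) nodes — the convention
under which a 93-node, 234-edge network has density 5.47% and mean degree
5.03 — with the all-node density reported alongside.

**Positivity labeling** (`fit_mixture_cutoff`, `assign_positivity`):
continuous biomarker levels are split by a two-component normal mixture
fitted with EM (tercile-based initialization, jittered restarts on
degeneracy). The threshold is the point between the component means where
the weighted component densities are equal (posterior 0.5), computed in
closed form as a quadratic root and cross-checked numerically. Values
strictly above the threshold are positive; the amyloid ratio is
reciprocal-transformed upstream (`reciprocal_abeta`) so that higher always
means riskier. Other component families (lognormal, gamma) are out of scope.

**Evaluation** (`repeated_cv`, `density_ablation`, metric functions): AUROC
is the Mann–Whitney pair statistic; AUPRC uses the average-precision
formulation (no linear interpolation — implementations differ, so this is
pinned); accuracy and F1 use a 0.5 threshold, matching the high-risk rule
used for the survival grouping. Cross-validation is stratified on the joint
label pattern, refits the model per fold, and recomputes the z-score
statistics on training folds only. The overall metric is the plain mean of
the four.

**Explainability** (`loo_importance`, `major_proteins`, `subset_risk`,
`effect_significance`): importance is leave-one-protein-out
$\Delta$AUROC — the protein's row of $Z$ is zeroed at prediction time, with
no refit, because the quantity of interest is the protein's contribution to
the *synergetic effect*; a node-removal re-propagation variant is available
behind `repropagate = TRUE`. Major proteins are the intersection of the
top-$\lceil 0.1 d\rceil$ sets by signed estimation parameter and by
importance, ties broken by protein id. Because the logit is linear in
$\theta$, subset risks from disjoint protein sets add on the logit scale —
a property the tests assert.

## The synthetic-data generator

`synth_dataset()` emulates exactly the world the model assumes: expression
$X \sim U(0,1)$ (mimicking the logistic-scaled range), a random weighted
graph at density 0.0547 (Erdős–Rényi or a planted-modules variant in which
within-module edges are five times likelier, mirroring the modular structure
of real PPI networks), synergy $Z = (\Phi+L)^{-1}\Phi X$ under planted
intensities, and labels $Y_b \sim \mathrm{Bernoulli}(\sigma(\theta_b^\top Z))$.
Defaults (113 proteins, 906 samples, 4 biomarkers) mirror the motivating
cohort's scale. Planted $\theta_b$ are orthogonalized against the mean
synergy profile: the model has no intercept, so an unconstrained draw would
shift prevalence toward 0 or 1; the projection keeps positivity balanced
while staying exactly representable by the model.

What a green test on this generator establishes: the estimator recovers the
generative mechanism it assumes (held-out AUROC within 0.05 of the
true-logit oracle; planted/recovered $\theta$ correlation $\ge 0.7$ at
$d = 30$, $n = 2000$). What it does not establish: performance on real
plasma panels, where expression is not uniform, the network is misspecified,
effects are not generated by the model, and prevalence sits near 20–25%.
$\phi$ is only weakly identified under weak signal — recovery of $\phi$ is
reported as a rank correlation under strong signal, not asserted as exact.

## Numerical choices and degenerate inputs

- $(\Phi+L)$ is solved by one Cholesky factorization reused across sample
  columns and the gradient solve; at $d \approx 113$ dense factorization is
  trivial and bit-stable, which makes refits deterministic.
- The closed form is verified against the fixed-point iteration
  $Z \leftarrow (\Phi+I)^{-1}(\Phi X + S Z)$, $S = D^{-1/2} W D^{-1/2}$,
  which contracts for any $\phi > 0$.
- Edgeless networks are valid inputs everywhere: $L = I$ and the model
  degrades to coordinate-wise shrinkage $Z_{ij} = \phi_i X_{ij}/(1+\phi_i)$
  (the independent-effect-only baseline of the density ablation).
- EM degeneracy (collapsing component) triggers up to three jittered
  restarts, then an error; the log-likelihood is asserted non-decreasing.
- Ties: kNN neighbour ties break toward the lower sample index; ranking ties
  in `major_proteins` break by protein id; tied scores contribute 0.5 to
  AUROC via average ranks.
- A mixture threshold falling outside $[\mu_1, \mu_2]$ (extreme mixing
  weights) falls back to a root search on that interval, then the midpoint.

## Design choices where the design was open

- **Optimizer duality.** The training loop is stated with plain gradient
  descent, while the experiments use ADAM (lr 0.001). Both are implemented;
  ADAM is the default, and the descent-property test pins plain GD.
- **Covariates.** The demographic extension (age, sex, education) is
  mechanism-unspecified upstream. Here standardized covariates enter each
  biomarker's logit additively with their own weights — never propagated
  through the graph, since they are not network nodes — and join the ridge
  term so the objective remains a single coherent penalized likelihood.
- **Graph value is regularization.** Because propagation is an invertible
  linear map of $X$, any linear-logit predictor expressible with the graph
  is expressible without it; with ample data the graph cannot improve the
  best fit. Its benefit is an inductive bias: with limited samples and a
  ridge penalty, the true predictor is cheapest to represent in the correct
  graph's coordinates. The edge-density ablation test therefore runs in an
  estimation-limited regime (60 proteins, 200 samples, $\delta = 0.01$),
  where mean AUROC rises with the retained edge fraction.

## Known limitations

- Welch t is not the moderated test used upstream; with small groups the
  two can disagree near the threshold.
- The importance measure is $\Delta$AUROC, not SHAP; the two rank similarly
  but are not interchangeable.
- $\phi$ recovery is weakly identified when the planted signal is weak; only
  $\theta$ recovery is asserted quantitatively.
- The generator does not emulate Olink NPX distributions, batch structure,
  or realistic demographics.
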