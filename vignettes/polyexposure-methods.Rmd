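---
title: "Exposure-wide scans and polyexposure risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-wide scans and polyexposure risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxscan)
```

## The problem

Environmental and behavioural exposures shape disease risk, but most
epidemiological analyses test one exposure at a time.  An exposome-wide
association study (XWAS) scans a large panel of exposures agnostically, one
covariate-adjusted regression each, in direct analogy to a GWAS over
environmental variables.  A polyexposure risk score (PXS) then aggregates
the selected exposures into a single per-individual quantity — a weighted
sum of exposure values whose weights come from a calibrated multivariable
model — so that the joint, mutually adjusted burden of many correlated
exposures can be carried into prediction, stratification and model
comparison.

`pxscan` implements this workflow for rectangular cohort tables with a
continuous (`lm`), binary (`logistic`) or censored survival (`cox`)
outcome.  The reserved columns are `ID`, `PHENO` and, for survival
analysis, `TIME`; `PHENO` doubles as the 0/1 event indicator in the
survival case, so a single schema covers all three families.  Every other
analysis column carries a role — *exposure* (a candidate for selection)
or *covariate* (forced adjustment, never selected, never scored).

## The scan

For each exposure $e$ the scan removes individuals with a missing value
or an *unwanted response* (user-declared invalid categorical codes such
as "prefer not to answer") in $e$ or in any covariate, and fits

$$ g\!\left(E[Y]\right) = \beta_0 + \beta_e\, e + \boldsymbol\gamma^\top
\mathbf{c} $$

in the designated family ($g$ the identity or logit link; a Cox partial
likelihood without intercept for survival).  Each model therefore has its
own complete-case $n$, which is reported.  A continuous exposure
contributes its slope's Wald p-value; a multi-level categorical exposure
contributes one likelihood-ratio p-value for all of its dummy terms
jointly, so every exposure yields exactly one test.  The per-exposure
p-values are corrected by the Benjamini–Yekutieli step-up procedure by
default: with $m$ tests and order statistics $p_{(i)}$,

$$ \tilde p_{(i)} = \min\!\Big(1,\; \min_{j \ge i}\; p_{(j)}\,
\frac{m\,c(m)}{j}\Big), \qquad c(m) = \sum_{j=1}^m \tfrac1j , $$

which controls the false-discovery rate under arbitrary dependence
between exposures — the relevant regime, since exposures are typically
correlated.  Benjamini–Hochberg ($c(m)=1$) and Bonferroni are available.
Models that fail (for example by complete separation, detected as fitted
probabilities pinned at 0/1) are reported with a flag, and excluded from
the correction so that $m$ counts only interpretable tests.

## Deriving a score

The derivation deliberately separates three disjoint groups of
individuals: selection (A), calibration (B) and validation (C).  Group C
individuals never influence any estimation step, so their scores and
metrics are honestly held out.

**Step 1 — penalized selection (Group A).**  A cross-validated
elastic net is fitted over the candidate exposures:

$$ \min_{\beta}\; \bar\ell(\beta) \;+\; \lambda \sum_j w_j\Big(
\alpha\,|\beta_j| + \tfrac{1-\alpha}{2}\,\beta_j^2 \Big), $$

with $\bar\ell$ the average negative (partial) log-likelihood of the
family, $\alpha = 1$ (lasso) by default, $\alpha = 0$ ridge, intermediate
values the elastic net.  Penalized exposure columns are standardized to
mean 0 and unit variance (coefficients are reported back on the original
scale); covariate columns have penalty weight $w_j = 0$ — they are forced
into every model, matching their role as adjustments.  The penalty path
has 100 log-spaced values from the analytic $\lambda_{\max}$ (the
smallest $\lambda$ with all penalized coefficients zero, from the KKT
bound on the null-model gradient) down to $10^{-3}\lambda_{\max}$, and
$\lambda_{\min}$ is the value minimizing the mean 10-fold
cross-validated deviance (squared error; binomial deviance; the
Verweij–van Houwelingen partial-likelihood deviance for Cox).  Folds are
a seeded partition, stratified by outcome class or event status.
Exposures with any nonzero coefficient at $\lambda_{\min}$ survive to
Step 2; selecting nothing is an error, by design — a null cohort should
abort rather than produce an empty score.

**Step 2 — backward stepwise calibration (Group B).**  The survivors
enter an unpenalized multivariable model.  While the largest per-exposure
p-value (Wald for single terms, likelihood-ratio for multi-level
categoricals) is at or above the threshold (0.05 by default), that single
worst exposure is removed and the model refitted; ties remove the later
exposure in input order.  Covariates are never candidates for removal.
The final model therefore contains only *independently* significant
exposures.  Complete cases are taken once, over the initial candidate
set, so successive fits are nested on identical rows — a deliberate
choice (the alternative, re-filtering after each removal, changes $n$
between nested fits and invalidates the likelihood-ratio comparisons).

**Step 3 — scoring and assessment (Group C).**  The score of individual
$i$ is the weighted sum over the model's exposure terms,

$$ \mathrm{PXS}_i \;=\; \sum_{t \in \text{exposure terms}} \hat\beta_t\,
x_{it}, $$

using the training-time dummy coding and standardization constants.
Covariate terms and the intercept are excluded: covariates adjust, they
do not score.  Individuals with a missing value, an unwanted response or
a categorical level unseen at training time are unscoreable and counted.
Assessment fits `PHENO ~ PXS + covariates` on Group C and reports
$R^2$, the AUC of the fitted probabilities, or Harrell's C-index of the
linear predictor, with a seeded percentile-bootstrap confidence interval.
Including the covariates in the assessment model is a choice: it measures
the score's contribution in the realistic adjusted setting rather than
its marginal association.

## Pairwise interactions with strong hierarchy

The interaction-aware variant replaces Step 1 with an overlapped group
lasso.  Every exposure has a main-effect group; every exposure pair
$(j,k)$ has an interaction group whose *latent* coefficient block
contains copies of both mains' columns plus their element-wise products.
With group weights $s_g = \sqrt{|g|}$ the objective

$$ \bar\ell(\theta) + \lambda \sum_g s_g\,\lVert \theta_g \rVert_2 $$

is convex, and a nonzero interaction group necessarily carries its two
main effects into the total coefficients — *strong hierarchy holds by
construction*, not by post-hoc filtering.  The problem is solved by
proximal gradient descent (FISTA) with the group soft-threshold proximal
step, a spectral step size, and adaptive momentum restarts; the
cross-validation machinery is shared with the elastic net.  Because the
group-lasso loss is linear/logistic only, survival cohorts run the
selection as a logistic model on the event indicator; Step 2 then
*recalibrates* an unpenalized model of the designated family (a Cox model
for survival) containing exactly the selected main and product terms plus
covariates.  There is no stepwise pruning in this variant — recalibration
only — which is why it can retain larger models and is the more
overfitting-prone of the two derivations; that behaviour is inherent to
the procedure and is reproduced, not repaired.  Product terms are
products of the parents' standardized values with constants taken from
the calibration data and stored in the model, so scoring is exactly
reproducible.

## Comparing models and stratifying risk

Goodness of fit is $R^2$, AUC (Mann–Whitney form, ties counted half) or
Harrell's C-index (over comparable pairs — the earlier time an observed
event — concordance of risk ordering, risk ties half, tied event times
not comparable; pair counting delegates to `survival::concordance`).
`delta_pred()` compares two prediction vectors by a *paired* bootstrap:
each replicate resamples individuals once and evaluates both models on
the same replicate, which is the variance-correct way to bootstrap a
difference; replicates on which a metric is undefined are redrawn.  The
delta distribution is summarized by a percentile interval (BCa offers
little at these replicate counts and costs transparency).
`risk_stratify()` reproduces the standard clinical read-out: a Cox (or
logistic) fit of top-decile membership gives the hazard (odds) ratio of
the top 10% of the score distribution against the rest, plus a 100-bin
percentile-vs-incidence table, where incidence is events divided by bin
size (a per-bin rate, not a cumulative one).

## The synthetic cohort generator

All tests run against seeded cohorts with known truth.  Exposures derive
from a latent Gaussian vector with exchangeable correlation $\rho$
(single common factor) — the simplest structure that exercises
inter-exposure correlation; continuous exposures are the latent values,
categorical exposures are quantile slices into equal-probability levels.
Covariates are age ($N(55, 8^2)$, standardized in the linear predictor)
and sex (Bernoulli(½)).  True effects act on the latent standardized
scale; outcomes follow the family: Gaussian noise of unit variance,
Bernoulli with logit link, or exponential event times with rate
$\lambda_0 e^{\eta}$ (proportional hazards by construction) under
independent uniform censoring.  Missingness is injected completely at
random into exposures only, and an unwanted code
(`prefer_not_to_answer`) into categoricals, at 2% each by default —
enough to exercise every filtering path without dominating $n$.

What the generator does *not* emulate: real marginal distributions
(skew, heaping, bounded scales), block or hierarchical correlation
structures, informative missingness, measurement error, or
non-proportional hazards.  Passing tests therefore demonstrate
correctness of the algorithms under their stated assumptions, not
robustness of the scientific conclusions to real-data pathologies.

## Numerical choices

* **Engines.**  Unpenalized fits use exact least squares, IRLS
  (tolerance $10^{-8}$, 100 iterations) and the Cox partial likelihood
  with the Efron tie correction.  Separation is flagged
  (`converged = FALSE`) and never silently repaired; downstream stages
  treat such fits as unusable.
* **Coordinate descent.**  The quadratic subproblems are solved by
  cyclic coordinate descent with covariance (Gram) updates, accelerated
  by exact active-face solves: a few sweeps settle the support and sign
  pattern, the penalized quadratic is then minimized exactly on that face
  by a linear solve, and the KKT conditions are verified globally before
  acceptance.  The per-sweep objective is non-increasing throughout.
  Coefficients below $10^{-10}$ are snapped to zero, which makes the
  all-zero solution at $\lambda \ge \lambda_{\max}$ exact.
* **Penalized Cox.**  The outer quadratic approximation uses the
  Breslow-form diagonal Hessian of the partial likelihood (the standard
  penalized-Cox device).  Because the diagonal approximation converges
  only linearly — and slowly under correlated designs — the fixed point
  is accelerated by a secant extrapolation accepted only when it improves
  the penalized objective.  Paths warm-start from the unpenalized-block
  (null) fit.
* **FISTA.**  Step size $1/L$ with $L$ from power iteration on the Gram
  matrix (divided by 4 for logistic loss), adaptive restarts on objective
  increase, relative-objective tolerance $10^{-9}$.  As a first-order
  method its iterates carry $\sim 10^{-5}$ coefficient error at
  convergence while objective values are accurate to $\sim 10^{-10}$;
  tests certify solutions through the KKT conditions, which is the
  sharper check.
* **Degenerate inputs.**  Constant exposure columns are dropped with a
  warning (an error if none survive); duplicated IDs, non-positive
  times, single-class outcomes and overlapping groups are errors;
  aliased product terms in the interaction recalibration are dropped
  with a warning, but rank deficiency among main terms is an error.
* **Serialization.**  Models and truths are written as JSON with 17
  significant digits, which round-trips IEEE doubles exactly; scores
  recomputed from a reloaded model are bit-identical.

## Problem sizes used in the checks

The test suite exercises the pipelines at sizes a laptop handles in
minutes, chosen to make the Monte-Carlo assertions stable: the
FDR/power study uses 200 replicates of a 50-exposure scan at $n = 2000$
(10 true exposures at standardized effect 0.3, independent exposures so
that marginal nulls are genuinely null — under correlated exposures a
"null" exposure has a nonzero marginal slope and a false-discovery
count would be ill-defined); parameter recovery uses 20 seeds of 20
exposures (4 true at 0.3, $\rho = 0.2$) with 2000 individuals per
derivation group; the bootstrap comparison uses 20 seeds at $n = 2000$
with $B = 1000$.  The acceptance script re-runs the same pipelines at
the same order of magnitude from a single command-line seed.

## Known limitations

Only pairwise interactions are considered — no three-way or higher
terms.  No imputation: complete-case filtering only, as specified by the
workflow.  No automatic variable transformation or recoding heuristics;
unwanted codes must be declared by the user.  No robust or clustered
standard errors, stratified or time-varying Cox models, or Firth
correction.  The interaction variant's susceptibility to overfitting
(no stepwise stage) is documented behaviour.
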