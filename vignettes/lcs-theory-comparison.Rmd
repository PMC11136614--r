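---
title: "Comparing common-cause and dynamic-mutualism accounts with latent change score models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing common-cause and dynamic-mutualism accounts with latent change score models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscomp)
```

## The modeling problem

Two influential accounts compete to explain why psychopathology symptoms
co-develop. Under a *common-cause* account, a single latent liability — a
general p factor spanning internalizing, externalizing, (reversed)
prosociality and ADHD in adolescence, or a depression factor spanning
affective-suffering and motivation symptoms in later life — generates all
change, and indicators move only because the liability moves. Under
*dynamic mutualism*, distinct domains causally feed each other's change,
and the familiar positive manifold is an emergent property of those
reciprocal interactions. Cross-sectionally the two stories produce
equivalent covariance structures, so the package follows the longitudinal
strategy: formalize each theory as a latent change score (LCS) structural
equation model, fit both to multi-wave panel data, and let model fit and
information criteria arbitrate.

## The latent change score algebra

For a construct $y$ at waves $t = 1, \dots, W$, fixing the autoregression
between successive occasions to 1 turns the occasion-$t$ residual into an
explicit change factor:

$$y_{t,i} = 1 \cdot y_{t-1,i} + \Delta y_{t,i}$$

Each change factor receives a free mean $\alpha_t$ (average change over
the interval), a free variance $\zeta_t$ (individual differences in
change), a *self-feedback* regression $\phi_t$ on the same construct's
previous level, and — in multivariate models — *coupling* regressions
$\gamma_t$ on other constructs' previous levels:

$$\Delta\eta_{1t,i} = \alpha_{1t} + \phi_{1t}\, y_{1,t-1,i} +
  \gamma_{1t}\, y_{2,t-1,i} + \zeta_{1t,i}.$$

The residual variance of every chain variable at waves $\ge 2$ is fixed to
0, so all residual variance is carried by the change factor; the level and
change-score means/variances at wave 1 are free, with equality over time
arranged so that any actual change is absorbed by the change factors.

Four builders produce the theory models as declarative specifications
(`lcs_spec` objects) with exact free/fixed/equality bookkeeping:

* `build_common_cause_pfactor()` — four correlated first-order factors per
  wave, a second-order p factor, and a univariate LCS chain on p;
  change-score covariances fixed to 0.
* `build_mutualism_multivariate()` — the same measurement layer, one LCS
  chain per domain, per-interval $\phi$ and all ordered-pair $\gamma$
  free, and all pairwise change-factor covariances free.
* `build_common_cause_depression()` — a one-factor model over parcel
  indicators with a univariate chain and baseline age as covariate.
* `build_mutualism_bivariate()` — the two parcel series modeled directly
  as construct scores (no measurement layer) with coupled chains.

## Identification and the degrees-of-freedom arbiter

Several constraint choices (marker variables, invariance level, the scope
of indicator-specific residual covariances) are estimation-equivalent in
spirit but change the free-parameter count. The package fixes them by a
single arbiter: the model degrees of freedom of all four preregistered
specifications and the freed-covariance variant must reproduce their
published values *simultaneously*, with df defined as $p(p+3)/2$ observed
moments (means included) minus free parameters after equality merging.

The conventions that satisfy all five at once:

* **Marker variables.** The first indicator of every factor has loading
  fixed to 1 and intercept fixed to 0 (likewise for the first first-order
  factor on p), so factor variances and wave-1 latent means are estimable.
* **Invariance.** Headline models are *strongly* invariant: loadings and
  intercepts equal over waves, residual variances free per wave. Strict
  invariance (equal residual variances) is a separate step of the
  invariance sequence, not the headline parameterization.
* **Indicator-specific residual covariances.** In the 42-item design each
  item's residuals covary freely across *all* wave pairs
  ($42 \times \binom{4}{2} = 252$ parameters). In the parcel design the
  analogous covariance is equality-constrained across wave pairs (one
  parameter per parcel). Per-cohort df matching is what decides this
  asymmetry; both scopes are exposed via the `resid_cov` argument.

```{r df}
count_free_parameters(lcs_model("zproso_cc"))   # df 13,835 at p = 168
count_free_parameters(lcs_model("share_mut"))   # df 8 at p = 11
```

Variants (`free-change-covariances`, `fixed-change-covariances`,
`age-on-change`, `gender-baseline-covariate`, invariance levels) rebuild
the specification from its stored design, so application is idempotent and
reversible. One genuinely ambiguous case deserves a note: the exploratory
age-on-change extension of the bivariate mutualism model is published with
only two added parameters although eight change factors exist. The package
reads that as one slope per domain, equality-constrained across intervals
(`age-on-change`); the unconstrained reading (one slope per change factor)
remains available as `age-on-change-free`, and reports state which was
used. For the univariate (common-cause) chain both readings coincide with
one free slope per change factor, matching the published four-parameter
step.

## Estimation engine

The engine is a RAM-parameterized maximum-likelihood SEM core: directed
paths in $A$, covariances in $S$, intercepts in $M$, implied moments
$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top$, $\mu = F(I-A)^{-1}M$.

* **FIML.** Rows are grouped by missingness pattern; each pattern
  contributes its Gaussian log-likelihood from per-pattern sufficient
  statistics. With zero missingness this equals complete-data ML exactly
  (a tested identity). Rows with no observed cell are dropped and counted.
* **Gradients.** Analytic, via the chain rule through the RAM structure;
  the finite-difference Hessian of that gradient supplies the observed
  information for standard errors and a condition-number diagnostic.
* **Optimization.** Quasi-Newton (`nlminb`) from scale-informed starts
  (unit loadings, zero regressions, variances at the observed scale,
  change means/variances at observed wave-to-wave differences), with up to
  5 seed-controlled jittered restarts. Convergence is declared from the
  per-observation gradient norm (tolerance `1e-4`); the solver's own code
  is recorded but not trusted, because flat directions among many free
  change-score covariances routinely trigger spurious "singular
  convergence" reports at a genuine optimum. Non-positive-definite implied
  covariances are treated as infeasible (barrier value), never silently
  repaired.
* **Saturated and baseline models.** Under missingness the saturated
  log-likelihood comes from an EM pass on the unstructured Gaussian model
  (tolerance `1e-8`, iteration cap 500, iterations logged); the
  independence-with-free-means baseline factors per column and is solved
  in closed form. $\chi^2 = 2(\ell_{sat} - \ell_{model})$.
* **Fit indices.** RMSEA uses the $N$ denominator with a 90% CI by
  noncentral-$\chi^2$ inversion; CFI uses the independence baseline (the
  published analyses do not state their baseline; independence-with-means
  is assumed and documented here); SRMR averages squared standardized
  residuals of means and covariances. Robust (sandwich/scaled)
  corrections are deliberately out of scope: the package reports plain
  ML/FIML statistics. Fit indices produced under MLR-style robust
  estimators are therefore not directly comparable with this package's,
  whereas degrees of freedom, nesting steps, and criterion-weight
  verdicts do not depend on the scaling correction.

Standardized coefficients follow
$\beta = b \cdot \mathrm{SD(predictor)}/\mathrm{SD(outcome)}$ with SDs
taken from the implied moments of the full roster (so change-factor SDs
are model-implied). Under equality constraints the first constrained
entry's SDs are used.

## Invariance testing

`invariance_sequence()` fits configural, weak (equal loadings), strong
(plus equal intercepts) and strict (plus equal residual variances) levels
and flags a violation when $\Delta\mathrm{CFI} = \mathrm{CFI}_{prev} -
\mathrm{CFI}_{cur}$ *strictly* exceeds .01 — a drop of exactly .010
passes. `partial_invariance_search()` then releases intercept equalities
one at a time until the partially constrained model sits within the
cutoff of the weak model. Candidates are selected by exhaustive
one-at-a-time refitting (largest $\chi^2$ drop) rather than analytic
modification indices: the selection target is identical and the exhaustive
version is trivially verifiable, at a cost that is acceptable for
desk-scale measurement models. Marker intercepts are never released, and
wave-1 intercepts keep the shared label so every release stays identified.

## Arbitration

`information_criteria()` implements $\mathrm{AIC} = -2\ell + 2k$ and
$\mathrm{BIC} = -2\ell + k\log N$ with $k$ the merged free-parameter count
and $N$ the rows used. `akaike_weights()` computes
$w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ on criterion
differences (numerically safe for arbitrarily large separations); applied
to BIC values these are Schwarz weights. `lrt()` verifies nesting by
label-set inclusion and treats a negative $\Delta\chi^2$ beyond `1e-6`
relative tolerance as a refit-required error rather than clamping it.
`compare_models()` assembles the comparison tibble and
`autoplot()` renders the normalized-probability bars.

## The synthetic-cohort generator

The generator is the package's stand-in for the two access-restricted
cohorts and defines its study conditions:

* **Adolescent-like preset** (`config_zproso()`): n = 1,482; 42 five-point
  Likert-like items over four correlated domains (13 internalizing, 12
  externalizing, 8 reverse-coded prosociality, 9 ADHD — the per-domain
  split is a package convention, since only the total is fixed by the
  design) and 4 waves; 11% MCAR missingness. Items are emitted as
  continuous by default, matching how the analyses treat them;
  `discretize = "likert-5"` exists to study rounding robustness.
* **Older-adult-like preset** (`config_share()`): n = 6,443; 12 binary
  EURO-D-style symptoms over 5 waves, Bernoulli draws through a probit of
  the domain latent with thresholds solved to hit target marginal
  prevalences (defaults spread over .10–.40); parcel sums of 8
  (affective suffering, range 0–8) and 4 (motivation, range 0–4) items;
  5.31% MCAR on the parcel scores; baseline age drawn N(61.5, 8.3²) with a
  small positive slope (0.012 per year, ≈ 0.1 standardized) on the
  baseline latents.
* **Population dynamics** (both worlds): baseline variances 1,
  inter-domain correlations 0.3, item loadings drawn once from
  U(0.4, 0.8), self-feedback −0.2, change means 0.2, change-residual
  variances 0.5; coupling 0 in the common-cause world and +0.2 for every
  ordered pair in the mutualism world. These are documented, realistic
  package defaults — the published analyses report no population values —
  and they are never presented as estimates of the real cohorts.

Common-cause worlds simulate the liability chain and expand it into
domain latents through second-order loadings plus wave-independent
disturbances (`expand_common_cause()`); mutualism worlds simulate the
coupled chains directly. The accounting identity
$y_t = y_{t-1} + \Delta y_t$ holds to machine precision for every record,
identical configurations reproduce byte-identical cohorts, and for
direct-score designs the simulated moments converge to the
`implied_moments()` of the matching specification — the
simulator/engine duality that the test suite checks at $n = 10^6$.

What the generator does **not** emulate: intervention arms, multi-country
sampling, MAR/MNAR missingness (MCAR only — exactly the regime in which
FIML's validity is being exercised), item-level floor effects beyond what
the probit emission induces, and any cohort-specific parameter values.
Passing recovery tests on these cohorts therefore validates the
*machinery*, not any substantive claim about the real data.

## Problem sizes used by the test and acceptance suites

Chosen once as desk-scale study conditions: the moment-duality check runs
at $n = 10^6$ on the direct bivariate design; parameter recovery uses 30
replicates at n = 2,000 with 10% MCAR; the likelihood-ratio size check
uses 250 replicates of a 2-wave null; model recovery uses 10 replicates
per world of the full 5-wave parcel preset at n = 1,500 (AIC weights are
expected to select mutualism in ≥ 90% of coupled-world replicates, and
BIC to prefer the common cause in a majority of single-liability
replicates — BIC's heavier penalty makes it conservative about the
38-parameter difference in the other direction, which is itself a
documented behavior, not a defect). The two 42-item specifications are
constructed and counted — that is what their published df pin down — but
never optimized in the suites: a 529-parameter fit is not a desk-scale
computation and nothing in the acceptance surface requires it.

## Known limitations

* Plain ML/FIML only: no robust corrections, no categorical-indicator
  likelihood (binary symptoms enter through parcels, as in the study
  design), no sampling weights, no multi-group models.
* The common-cause/mutualism comparison is non-nested; the package
  follows the weights-based arbitration and reserves `lrt()` for genuinely
  nested variant pairs.
* Modification-index selection by exhaustive refitting scales quadratically
  in candidate intercepts; for very large item sets an analytic score test
  would be the natural upgrade.
* df can be negative for deliberately over-parameterized custom
  specifications; `count_free_parameters()` reports and flags this rather
  than refusing.
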