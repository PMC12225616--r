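---
title: "Estimating dyadic discrepancy: raw differences, empirical-Bayes slopes, and SEM factor scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dyadic discrepancy: raw differences, empirical-Bayes slopes, and SEM factor scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsim)
```

## The problem

A dyad is a pair of individuals nested in a relationship — spouses, a parent
and a child, a patient and a caregiver. Many questions in psychology and
epidemiology turn on the *discrepancy* between the two members' scores on a
construct (marital satisfaction, acculturation, desired intensity of medical
care): how large it is for each dyad, which member is higher, and how well it
predicts some outcome. With only two observations per cluster and
measurement error in both, the choice of estimator for the per-dyad
(idiographic) discrepancy is not innocuous.

`dyadsim` implements three estimators in common use and a Monte Carlo
harness for comparing them under controlled conditions:

* **RSD** — the raw score difference between the observed member scores.
* **EBD** — the empirical-Bayes (BLUP) slope of a two-level
  random-coefficient model.
* **SEM** — the slope-factor score of a two-indicator latent
  intercept/difference model.

## The generating model

Member $i \in \{A, B\}$ of dyad $j$ is assigned a reporter code
$r_{ij} = \mp 0.5$, and scores are generated from

$$y_{ij} = \gamma_{00} + u_{0j} + \beta_{1j} r_{ij} + e_{ij}, \qquad
  \beta_{1j} = \gamma_{10} + u_{1j},$$

with $u_{0j} \sim N(0, \tau_{00})$, $u_{1j} \sim N(0, \tau_{11})$ and
member-specific measurement error $e_{ij} \sim N(0, \sigma^2_{e_i})$. The
design factors map onto the components as

* conditional ICC $\rho$: $\tau_{00} = \rho\,\sigma^2_{true}$ (default
  total true variance 1), the share of true variance between dyads after
  conditioning on the reporter;
* effect size $d$: the grand discrepancy $\gamma_{10} = d\,\sigma_{true}$;
* effect-size variance: $\tau_{11}$, the spread of true discrepancies;
* reliability $\alpha_i$:
  $\sigma^2_{e_i} = (1-\alpha_i)/\alpha_i \cdot \sigma^2_{true}$ (0.4286 for
  $\alpha = .7$, 0.25 for $\alpha = .8$; the published design table rounds
  the former to 0.43).

The signed true discrepancy is $d_{true,j} = y^{true}_{Bj} - y^{true}_{Aj}$,
which under the default generation model ("A") equals $\beta_{1j}$ exactly.
A second model ("B") adds member-level true residuals with variance
$(1-\rho)\sigma^2_{true}$, so the conditional ICC of the true scores equals
the design label by construction; we expose both because the source study's
description is compatible with either bookkeeping, and model A is the one
whose closed-form RSD reliability,
$\tau_{11} / (\tau_{11} + \sigma^2_{e_A} + \sigma^2_{e_B})$, matches the
reliability levels that study reports. Neither model is asserted as the
original procedure; the choice is a package default, switchable in
`run_study()`.

Defaults left open by the source material, chosen once: $\gamma_{00} = 0$
(every estimator and metric is location-invariant) and $\tau_{01} = 0$ (no
generating intercept–slope covariance).

## The three estimators

**RSD.** $\widehat{D}_j = y_{Bj} - y_{Aj}$. Unbiased for $d_{true,j}$, with
variance inflated by both error variances. All three estimators are oriented
B $-$ A, matching the reporter coding, so they estimate the same signed
quantity.

**EBD.** With two observations per dyad the random-coefficient model is
unidentified unless the level-1 residual variance is fixed; we condition on
the measurement error ME, either the generating (design) values or
$(1-\bar\alpha) s^2_w$ estimated from the pooled within-dyad variance
(`measurement_error()`). Because every dyad shares the design matrix
$X = \bigl[\begin{smallmatrix}1 & -0.5\\ 1 & 0.5\end{smallmatrix}\bigr]$,
the Gaussian marginal likelihood profiles to a 2×2 covariance-matching
problem: the unconstrained maximiser is
$T_0 = X^{-1}(S - \mathrm{diag}(ME))X^{-\top}$ with $S$ the ML sample
covariance of $(y_A, y_B)$. When $T_0$ is positive semi-definite it is the
ML estimate; otherwise the optimum lies on the PSD boundary and is found
numerically over a Cholesky parameterization (tolerance $10^{-8}$ on the
scaled log-likelihood, 500 iterations, warm-started from the projection of
$T_0$ onto the cone). Scores are the BLUPs
$\hat\gamma_{10} + [\,\hat T X^\top \hat V^{-1}(y_j - X\hat\gamma)\,]_2$.
With diagonal $\hat T$ and equal error variances this reduces to the
textbook shrinkage form $\lambda\,\mathrm{RSD}_j + (1-\lambda)\hat\gamma_{10}$
with $\lambda = \hat\tau_{11}/(\hat\tau_{11} + 2\sigma^2_e)$ — a property the
test suite asserts exactly. Boundary solutions are flagged, never dropped:
over-shrinkage (all scores collapsing toward the grand slope) is the
phenomenon of interest, not a nuisance.

**SEM.** The latent intercept/difference model with loadings fixed at 1 and
$\mp 0.5$ and residual variances fixed at ME (two indicators cannot identify
free residuals: five observed moments against seven parameters). The latent
means and the full symmetric latent covariance $\Psi$ are free, and with a
square loading matrix the ML solution is closed-form (the implied covariance
saturates $S$). Two score extractions are available:

* `scoring = "bartlett"` (default): unshrunken weighted-ML scores, which
  with two indicators equal the raw difference for the slope factor;
* `scoring = "regression"`: posterior-mean scores
  $\hat\mu + [\,\hat\Psi \Lambda^\top \hat\Sigma^{-1}(y_j - \hat\mu_y)\,]_2$,
  identical to the EBD BLUPs whenever $\hat\Psi$ is PSD (same likelihood,
  same scoring formula — also asserted to $10^{-6}$ in the tests).

The default is the unshrunken extraction, and this is a deliberate,
consequential choice. Any posterior-mean score has variance strictly below
$\tau_{11}$, so its reliability metric (below) necessarily exceeds 1; the
study this package re-examines reports SEM reliability of about 0.53 —
slightly *under* 1 and close to RSD — which is only consistent with an
unshrunken extraction. Defaulting to Bartlett scores reproduces the
reported SEM behaviour; the regression extraction remains available for
studying the EBD-equivalence regime.

## Outcome generation and the prediction stage

A continuous outcome is generated per dyad,
$$Z = 0.5 + 0.8\,|D| + 0.5\,W + 0.2\,|D|\,W + \varepsilon,\qquad
  \varepsilon \sim N(0, 1),$$
for distinguishable dyads ($W$ indicates which member is higher, 1 when A
$\ge$ B), and $Z = 0.5 + 0.8|D| + \varepsilon$ for indistinguishable ones.

What $D$ and $W$ are is the single most consequential ambiguity in the
source material, whose generating equation is printed in terms of the plain
member scores $X$ and $Y$. `generate_outcome()` therefore supports both
readings:

* `basis = "observed"` (default): $D$ and $W$ come from the observed
  scores. This literal reading reproduces the published prediction-stage
  results — discrepancy-slope coverage near 95% (reported 91%) and power
  0.98 (reported 0.96) for RSD, and coverage collapsing to ~24% (reported
  24%) for EBD, whose shrunken scores inflate the slope estimate.
* `basis = "true"`: $D$ and $W$ come from the true scores. Under this
  reading the true-score benchmark regression is exactly the generating
  model — the regime in which coverage calibration (95%) and the
  errors-in-variables attenuation inequality hold, and the one the test
  suite uses for those properties. It does not, however, reproduce the
  published coverage/power/R² results by a wide margin, which is why it is
  not the default.

Neither basis reproduces *every* published summary: the reported R² bias
(−0.04) and slope biases (−0.26, −0.29) would require an attenuation level
incompatible with the reported coverage and power under any single basis we
could construct. The acceptance machinery reports what the implementation
actually computes.

Each method's absolute scores $|\widehat D_j|$ (with direction indicator and
interaction for distinguishable dyads) enter an OLS regression of $Z$ with
Wald 95% intervals. The direction indicator in these regressions is itself
configurable (`direction_source`): from the observed raw scores (default —
the same indicator for every method, and what a practitioner can actually
compute), from the sign of each method's own scores, or from the true
scores. Collinear terms (a constant direction in a replication) are flagged
inestimable and excluded from power/coverage denominators with counts.

## The metric battery

Per condition × method, aggregated over replications by `cell_metrics()`:

* **Discrepancy bias**: mean of estimate − truth (signed; the published
  tables label it "absolute bias" but print signed values).
* **Reliability**: mean over replications of the within-replication ratio
  Var(true)/Var(estimate) — 1 is ideal, values > 1 indicate shrinkage;
  aggregated as a mean of per-replication ratios, with total-shrinkage
  replications (zero estimate variance) excluded as infinite sentinels and
  counted.
* **Slope bias, SE bias, power, coverage** per regression coefficient
  against the generating values (0.8, 0.5, 0.2); SE bias compares the mean
  reported SE with the empirical SD of the estimates.
* **R² bias** against the true-score regression, and the overall model-F
  power.

`flag_ebd_outliers()` implements the post-hoc over-shrinkage diagnosis:
EBD values falling outside the observed RSD∪SEM range of a metric,
cross-tabulated by ICC and cluster number (fixed bounds are an option).

`eta_squared_anova()` decomposes any outcome over the design factors
(main effects and two-way interactions; higher-order variation folds into
the residual) as $\eta^2 = SS_{effect}/SS_{total}$, requiring the balanced
layout the design guarantees, on replication-level records by default.
`run_posthoc_anovas()` repeats this per method.

## Reproducibility and problem sizes

`run_study()` derives each replication's seed from (master seed, condition
index, replication index) by a counter scheme, so results are bit-identical
across condition orderings and degrees of parallelism; the manifest records
the full configuration. The default of 50 replications per cell (~10⁴
datasets over the 216-cell grid) is the reduced preset used throughout the
package's own tests and in `scripts/acceptance.R`; the published protocol
(1000 per cell) is a single argument away and scales linearly (roughly
35–40 minutes on one core).

## Numerical notes and degenerate inputs

* ML throughout (no REML), matching the source study's estimation choice.
* EBD: PSD constraint via Cholesky; boundary flagged at eigenvalue
  $< 10^{-8}$; a singular marginal covariance (possible only with zero ME
  and a degenerate sample) is an error.
* SEM regression scoring errors on a singular implied covariance; Bartlett
  scoring has no such failure mode.
* Ties in direction indicators ($X = Y$) count as $W = 1$ per the $\ge$
  convention; they have probability zero under continuous generation.
* `measurement_error(mode = "data")` pools within-dyad variances with one
  degree of freedom per dyad and uses the mean of the two reliabilities
  when they differ.
* A constant ANOVA outcome yields all-zero $\eta^2$ (0/0 defined as 0, with
  a warning); non-finite outcome values are dropped with a count.

## What the simulation does and does not show

The generator emulates bivariate-normal true scores with homoscedastic,
uncorrelated measurement error calibrated to two reliability levels, and a
linear outcome with standard-normal noise. Real dyadic data bring skewness,
floor/ceiling effects, correlated errors between members (the closed-form
`diff_score_reliability()` accepts an error correlation, but the generator
does not produce one), item-level measurement structure, and missing
members — none of which are modelled here, and missing-data handling is
explicitly out of scope. Passing tests therefore certify the estimators'
behaviour under the stated Gaussian conditions, not robustness beyond them.
Cluster sizes other than 2 are intentionally unsupported.
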