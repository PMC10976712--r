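---
title: "Latent-outcome mediation by covariance-structure modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-outcome mediation by covariance-structure modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentmed)
```

## The scientific problem

Preventive migraine treatments are usually judged by the reduction in
monthly migraine days (MMDs), but patients' health-related quality of life
(HRQoL) improves for reasons that migraine-day counts alone do not capture:
less nausea, less severe pain, improvement in whatever symptom the
individual patient finds most bothersome (the PI-MBS score). `latentmed`
implements the structural-equation machinery needed to ask *how much of a
randomized treatment's effect on HRQoL flows through each efficacy
mediator*, when HRQoL itself is not observed directly but measured by the
three Migraine-Specific Quality of Life Questionnaire (MSQ) domain change
scores: Role Function-Restrictive (RR), Role Function-Preventive (RP), and
Emotional Function (EF).

The model has three parts:

1. **Measurement model.** A single latent variable $\eta$ (HRQoL change)
   with three indicators,
   $y_j = \lambda_j \eta + \varepsilon_j$, $j \in \{EF, RP, RR\}$.
   The first indicator listed (MSQ-EF by convention here) is the *marker
   variable*: $\lambda_{EF} = 1$ fixes the latent's scale, so its
   reported standard error is exactly 0.
2. **Structural model.** Mediator change scores $m_k$ are regressed on
   the randomized treatment indicator $t \in \{0, 1\}$
   ($m_k = a_k t + u_k$), and the latent outcome on treatment and
   mediators ($\eta = c' t + \sum_k b_k m_k + \zeta$). Mediator residuals
   may covary.
3. **Mediation decomposition.** Each mediator's indirect effect is the
   product $a_k b_k$; the total effect is $c' + \sum_k a_k b_k$, and each
   component's percent contribution is its raw-scale share of the total.

## Estimation

The model is translated into RAM form (`to_ram()`): a directed-path matrix
$A$, a covariance matrix $S$, and a filter $F$ selecting observed rows,
with implied covariance
$\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top$.
Estimation minimizes the normal-theory discrepancy

$$F_{ML}(\theta) = \log|\Sigma| + \operatorname{tr}(S_{obs} \Sigma^{-1})
  - \log|S_{obs}| - p$$

with `stats::nlminb()` and an analytic gradient
($dF = \operatorname{tr}[\Sigma^{-1}(\Sigma - S_{obs})\Sigma^{-1}\,d\Sigma]$
expanded per free cell of $A$ and $S$). A model is fitted only if the
order condition holds: the number of free parameters cannot exceed the
$p(p+1)/2$ distinct observed moments.

Numerical choices, made once and kept:

* **Start values**: loadings 1, regressions and covariances 0, variances
  from the sample (halved for endogenous residuals). Deterministic, so a
  fit is bitwise reproducible.
* **Convergence**: gradient max-norm below $10^{-6}$ (or `nlminb`'s own
  clean exit with max-norm below $10^{-4}$); `rel.tol` is set to
  $10^{-12}$, far tighter than the 3-decimal reporting precision.
  `nlminb`'s "singular convergence" return merely signals that this
  relative tolerance is unreachable in double precision and is accepted
  when the gradient norm is small.
* **Non-positive-definite excursions** during optimization return a large
  finite objective so the optimizer backtracks rather than aborts.
* **Standard errors** come from the observed information,
  $(\text{scale}/2) \times \nabla^2 F_{ML}$ at the optimum, with the
  Hessian obtained by central differences of the analytic gradient.
* **Chi-square convention**: scale $= n - 1$ (Wishart) by default,
  switchable to $n$; the information matrix, RMSEA denominator, and
  log-likelihood use the same scale for internal consistency.
* **Heywood cases** (negative variance estimates) are reported with a
  recorded warning, not bounded away, so diagnostics stay visible;
  `bound_variances = TRUE` constrains them when wanted.
* **Missing data**: listwise deletion before computing moments, with the
  deleted row count logged. Full-information ML is out of scope because
  the data this design targets have low missingness.

## Standardization and fit evaluation

Standardized estimates rescale a raw coefficient by the ratio of the
predictor's to the outcome's standard deviation, both taken from the
*model-implied* covariance of the full variable vector so latent
variables are standardized too. The identity
`raw = std * sd(outcome) / sd(predictor)` is exact and tested to
$10^{-10}$.

Fit indices follow the conventional definitions: $\chi^2 =$ scale
$\times F_{ML}$; CFI against the independence baseline (all covariances
zero — fitted in closed form); RMSEA with the $(n-1)$ denominator
matching the chi-square convention; SRMR as the root mean square of
correlation-metric residuals over all $p(p+1)/2$ unique cells including
the diagonal; AIC $= -2\log L + 2k$. Saturated models take the limits
CFI $= 1$, RMSEA $= 0$. Adequacy flags apply strict inequalities at the
conventional cutoffs $\chi^2/df < 2.0$, CFI $> 0.9$, RMSEA $< 0.05$,
SRMR $< 0.08$; the baseline model definition is the standard independence
model, chosen because the analysis this package reimplements does not
state one.

## Mediation inference

Indirect-effect standard errors use the first-order delta method. The
default is the independence (Sobel) form
$\sqrt{b^2 se_a^2 + a^2 se_b^2}$, which reproduces the published
MMD-route inference exactly from printed inputs; `se_method = "full"`
uses the fitted parameter covariance (including $a$–$b$ covariances and
the stacked gradient for summed indirect and total effects), which is the
better choice when the fit object is available. Percent contributions are
computed on the raw (unstandardized) scale, because published percent
columns correspond to raw ratios; reports round half-up to integers while
machine output keeps full precision. A zero total effect makes
percentages undefined and is flagged rather than silently divided.

One orientation note: a beneficial treatment *lowers* symptom mediators
(negative $a_k$) while lower symptoms *raise* HRQoL (negative $b_k$), so
indirect effects come out positive. Abstract-style effect sizes are
sometimes quoted with the opposite sign (improvement direction); this
package reports the table orientation (positive totals) throughout.

Backward elimination refits the model after removing, one at a time, the
mediator whose outcome-association p-value is largest and at or above
`alpha` (strictly smaller p-values are retained), dropping its treatment
path and covariances with it. One-at-a-time removal (rather than batch)
keeps the procedure deterministic and standard. Protected variables —
always including the treatment — are never candidates.

## The synthetic-trial generator

No patient-level data are distributable, so `default_truth()` +
`generate_trial()` produce a synthetic trial with the statistical
structure the analysis assumes: 892 patients, 299:593
placebo:active block allocation (both doses of the active arm pooled and
coded 1), treatment effects on mediators and latent outcome equal to the
bundled published coefficient table, and a three-indicator measurement
model with standardized loadings near 0.78–0.93.

The published tables print coefficients but not variances, so the
generator *derives* them: treatment variance from the allocation
($p(1-p)$ with $p = 593/892$), each mediator's standard deviation from
its raw/standardized coefficient pair
($sd_m = |a_m|\, sd_t / |a_m^{std}|$), the latent outcome's standard
deviation as the median of the per-path estimates
$|b_m| sd_m / |b_m^{std}|$ (which agree with each other to about 1%),
and residual variances by subtraction. With this calibration a large
generated sample refits to the published standardized solution within
0.02. Choices without a published value:

* **Mediator residual correlation** is exchangeable at 0.3 — the
  diagrams of the source analysis free these covariances but print no
  values; 0.3 is a realistic moderate correlation among symptom change
  scores and is positive definite for all model sizes here.
* **Missingness defaults to zero.** The published per-visit missingness
  (2.5–6.1%) applies to visit-level records, while the generator emits
  one averaged change record per patient, which is nearly complete;
  `apply_missingness()` adds MCAR masking when a study of missingness is
  wanted.
* **Allocation is deterministic block** (exactly 299:593 at n = 892) so
  tests are stable; Bernoulli mode is available.
* **One record per patient** (the average change from baseline over the
  double-blind period), treated as independent rows. A pooled-visits
  mode with within-patient correlation was considered and rejected as a
  default because the visit-level correlation structure is unreported;
  modeling it would add unverifiable knobs to every downstream test.
* **PI_MBS is generated as a continuous Gaussian** by default (the SEM
  treats it linearly); optional discretization to the 7-point −3..+3
  scale is available. Proportion-type symptom mediators are likewise
  continuous and unbounded by design — the estimator is linear in them,
  and truncation would distort the calibrated covariances.

What passing tests on generated data do **not** show: robustness to the
non-normality, floor/ceiling effects, and informative missingness of real
patient-reported outcomes, nor the visit-level autocorrelation that the
per-patient averaging hides. The generator validates the estimator and
the decomposition algebra, not the clinical conclusions.

## Verification strategy and problem sizes

The test suite pins every layer to an independent route: closed-form
regression for latent-free path models ($10^{-6}$), a per-observation
multivariate-normal density oracle for the discrepancy ($10^{-10}$), a
Monte-Carlo product-SD oracle for the Sobel formula, a path-enumeration
oracle for total effects ($10^{-10}$), and direct formula recomputation
for fit indices. Parameter recovery uses one generated trial of
$2 \times 10^5$ rows (every free parameter within 3 SEs of truth) and SE
calibration uses 500 replicates of 5,000 rows (mean reported SE within
10% of the empirical SD; the treatment-variance parameter is excluded
because block randomization leaves its sample variance essentially
without sampling variability). The backward-elimination operating
characteristic uses 100 seeded replicates of 4,000 rows with one
true-null mediator. These sizes keep the full suite around a minute on a
single CPU while leaving Monte-Carlo margins well inside the asserted
tolerances.

The bundled worked example (`worked_example_check()`) recomputes every
cell of the published mediation table that is an arithmetic function of
the published coefficient table. Published inputs are rounded to 3
decimals, so each recomputed cell is compared within the first-order
propagation of the ±0.0005 input rounding (plus half an output ulp) —
never wider. Summary-row standard errors are reported but not judged:
they require the unpublished parameter covariance matrix.

## Known limitations

* Mean structures, multi-group models, ordinal/threshold indicators, and
  full-information ML for missing data are not implemented.
* The order condition is necessary, not sufficient: `check_identification()`
  cannot detect empirical under-identification, which surfaces instead as
  a singular information matrix (reported per-parameter as `NA` SEs).
* Dataset-dependent index values of the original analysis (its CFI,
  RMSEA, AIC magnitudes) are not reproducible without the raw trial data
  and are treated as context only; the package verifies the formulas and
  threshold logic, not those numbers.
* Robust/sandwich and bootstrap standard errors are out of scope; with a
  binary exogenous treatment the normal-theory SEs for path coefficients
  remain well calibrated (verified by simulation), but variance-parameter
  SEs inherit the usual normal-theory kurtosis sensitivity.
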