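# latentmed

Latent-outcome mediation analysis by structural equation modeling, for
randomized trials where the outcome — health-related quality of life
(HRQoL) — is not observed directly but measured through multiple
patient-reported indicators.

## The problem and who it is for

Preventive migraine treatments are typically judged by the reduction in
monthly migraine days (MMDs), yet patients' quality of life improves
through more channels than day counts: symptom severity, nausea, light
sensitivity, or whatever symptom the individual patient identifies as most
bothersome (PI-MBS). Biostatisticians analyzing such trials need to split
the treatment's total effect on HRQoL into a *direct* component and
*indirect* components flowing through each efficacy mediator — with the
outcome defined as a latent variable measured by the three
Migraine-Specific Quality of Life Questionnaire domain change scores
(MSQ-RR, MSQ-RP, MSQ-EF).

The model, in the field's standard notation, combines

- a measurement model `HRQoL =~ MSQ_EF + MSQ_RP + MSQ_RR` (marker loading
  fixed to 1, so standardized loadings come out around 0.78–0.93),
- structural regressions `m_k ~ Treatment` and
  `HRQoL ~ m_1 + ... + m_K + Treatment`, and
- the product-of-coefficients decomposition: indirect effect of mediator
  `k` is `a_k * b_k`, total effect `c' + sum(a_k * b_k)`, with
  delta-method (Sobel) standard errors and raw-scale percent
  contributions.

Everything is estimated by maximum-likelihood covariance-structure
fitting (RAM formulation, `nlminb` optimizer, analytic gradient), with
standardized solutions, fit indices (chi-square/df, CFI, RMSEA, SRMR,
AIC), AIC model ranking, and backward elimination of non-significant
mediators. A seeded synthetic-trial generator reproduces the statistical
structure of a 2:1 randomized migraine-prevention trial (n = 892,
299:593 allocation) calibrated to the bundled published coefficient
tables, so the whole pipeline is testable without patient-level data.

## Worked example

Generate a synthetic trial at the study's size, fit the
PI-MBS + MMDs model, and decompose the treatment effect:

```r
library(latentmed)

cfg   <- default_truth("model2")          # truth calibrated to published tables
trial <- generate_trial(cfg, seed = 1)    # 892 patients, 299:593 allocation
fit   <- fit_sem(trial, canonical_model("model2"))

fit_indices(fit)
#> chi-square = 4.087 on 6 df (chi2/df = 0.681), n = 892
#> CFI = 1.0000, RMSEA = 0.0000, SRMR = 0.0068, AIC = 31009.7
#> adequacy: chi_over_df pass, cfi pass, rmsea pass, srmr pass

decompose_effects(fit, "Treatment", "HRQoL")
#> Mediation decomposition: Treatment -> {MMDs, PI_MBS} -> HRQoL (SEs: independence)
#>           effect estimate    se      z p_value std_estimate pct_of_total
#>           direct    1.924 1.185  1.623   0.105        0.049           14
#>    indirect:MMDs    2.708 0.460  5.884  <0.001        0.069           19
#>  indirect:PI_MBS    9.278 0.868 10.685  <0.001        0.235           67
#>   indirect_total   11.986 0.983 12.196  <0.001        0.304           86
#>            total   13.910 1.540  9.034  <0.001        0.353          100
```

Reading the output: the model fits the generated covariances well (all
four adequacy flags pass); the treatment improves HRQoL by 13.9 points
total on the MSQ-EF scale in this replicate, of which 67% flows through
improvement in the patient's most bothersome symptom, 19% through
migraine-day reduction, and 14% is direct (unexplained by the modeled
mediators) — one seed's sampling fluctuation around the generating truth
(69% / 17% / 13%).

`worked_example_check()` needs no simulation at all: it recomputes every
arithmetic cell of the bundled published mediation table from the
bundled published coefficients (products, sums, Sobel SEs, z scores,
integer percents) and verifies each at the precision the printed inputs
support:

```r
head(worked_example_check(), 4)
#>    model        effect     quantity recomputed published   tolerance checked pass
#> 1 model1 indirect:MMDs     estimate  4.3813800     4.381 0.002738000    TRUE TRUE
#> 2 model1 indirect:MMDs std_estimate  0.1086610     0.109 0.000831000    TRUE TRUE
#> 3 model1 indirect:MMDs           se  0.6307068     0.631 0.002203017    TRUE TRUE
#> 4 model1 indirect:MMDs            z  6.9467782     6.943 0.019058151    TRUE TRUE
```

The end-to-end pipeline (data or generator -> optional backward
elimination -> fits -> indices -> mediation -> report files) runs from a
single config via `run_analysis()`, or from the shell via
`inst/cli/latentmed.R {run|simulate|fit|mediate|check}`.

## Package layout

- `R/model_syntax.R`, `R/ram.R` — model syntax parser, RAM translation,
  identification checks
- `R/estimator.R` — sample moments, ML discrepancy, `fit_sem()`,
  standard errors
- `R/evaluation.R` — standardization, fit indices, AIC comparison,
  backward elimination
- `R/mediation.R` — effect decomposition, Sobel SEs, percent
  contributions
- `R/simulate.R` — synthetic-trial generator calibrated to the bundled
  published estimates
- `R/pipeline.R` — end-to-end runner, worked-example check, I/O
- `vignettes/latent-mediation-methods.Rmd` — the model, numerical
  choices, generator calibration, and verification strategy
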