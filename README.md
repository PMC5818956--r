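# lcjoint

Joint modeling of longitudinal biomarker trajectories and time-to-event
outcomes in **heterogeneous populations** — cohorts that are a mixture of
latent subgroups, each with its own trajectory shape and baseline risk.
The motivating setting is HIV/AIDS cohorts, where repeated CD4 counts are
recorded together with time to death and subgroups differ in both.

## What it implements

For a population of `G` latent classes, with membership following a
multinomial logistic model on baseline covariates, the package models,
within class `g`,

* the biomarker by a random-intercept linear mixed model whose
  error-free part is the *trajectory*
  `Z*(t) = β₀g + β₁g t + β₂g x₁ + β₃g x₂ + b`, and
* the hazard by Weibull proportional hazards linked to the current
  trajectory value,
  `h(t | g) = αg λg t^(αg−1) exp(δg x₁ + γg Z*(t))`,

with `γg` the association parameter between the two processes.  Three
analysis strategies share this data layout:

| Strategy | Functions | Idea |
|---|---|---|
| **PA** (two-stage) | `fit_lcmm()` → `fit_joint()`, or `run_pa()` | classify subjects by a latent-class mixed model, then fit the full shared-trajectory joint model in each class; no conditional-independence assumption |
| **SA** (separate) | `fit_lmm()` + `fit_extended_cox_tv()`, or `run_sa()` | per-class mixed model plus extended Cox model with the observed (error-prone) measurements as a time-varying covariate |
| **JLCM** (one-stage) | `fit_jlcm()`, `select_num_classes()`, or `run_jlcm_approach()` | joint latent class model under conditional independence; class count chosen by BIC |

A simulation engine (`lcj_parameters()`, `lcj_design()`,
`generate_dataset()`, `calibrate_scale()`) draws heterogeneous cohorts
with event times obtained by inverting the cumulative hazard, and a
replication harness (`align_classes()`, `summarize_replications()`,
`run_experiment()`) computes bias, model-based and empirical standard
errors, 95% coverage probabilities and misclassification rates across
scenarios.  All estimators are classed S3 objects with `print`, `coef`
and `logLik` methods.

## Worked example

Simulate a two-class cohort of 300 subjects with strong association
(`γ = 0.5`), calibrating the Weibull scales so each class sees roughly
60% censoring, then run the two-stage approach:

```r
library(lcjoint)

params <- lcj_parameters(association = c(0.5, 0.5))
params <- calibrate_scale(params, lcj_design(300), target_censoring = 0.6,
                          seed = 1, per_class = TRUE)$params
cohort <- generate_dataset(lcj_design(300, seed = 42), params)
cohort
#> lcj_data: 300 subjects, 2039 longitudinal measurements,
#>   34.7% events (65.3% censored)

pa <- run_pa(cohort, n_classes = 2, seed = 42)
pa <- align_classes(pa, cohort$survival$true_class)
pa
#> PA approach result (2 classes)
#>   misclassification vs truth: 0.023
#> Estimates:
#>        Intercept    t_ij      X1      X2 var(b) surv_X1  gamma
#> class1    0.9482 -1.0271  0.4272  0.9306 0.9333  0.4185 0.4738
#> class2   -1.0278  0.9977 -0.4812 -0.9472 0.9249 -0.9097 0.6981
```

Only 2.3% of subjects are misclassified, and the per-class estimates sit
near the generating values (class 1: intercept 1, slope −1, `x1` 0.5,
`x2` 1, `var(b)` 1, `δ` 0.5, `γ` 0.5).  The class-1 joint fit carries
model-based standard errors for every parameter, variances included:

```r
pa$fits[[1]]
#> Shared current-value joint model
#>   151 subjects, 50 events, 15 quadrature nodes, logLik -1637.950
#>               estimate         se
#> (Intercept)  0.9481821 0.15080243
#> time        -1.0271230 0.02682789
#> x1           0.4271627 0.18156263
#> x2           0.9306435 0.09837767
#> var(b)       0.9332827 0.13417333
#> sigma2       1.0651400 0.05251943
#> surv_x1      0.4185177 0.30669675
#> gamma        0.4738111 0.11482729
#> shape        0.5952760 0.08470539
#> scale        0.1059227 0.03152510
```

The association estimate (γ̂ = 0.47, SE 0.11) recovers the generating
value 0.5; the same data analysed with the separate approach
(`run_sa()`) attenuates it toward zero because the extended Cox model
plugs in the noisy observed measurements instead of the trajectory.

User data enter through the same layout: `read_dataset()` loads the
paired CSVs (long-format measurements; one-row-per-subject survival),
and `scripts/lcjoint-cli.R` offers `simulate` / `fit` / `experiment`
subcommands for shell use.

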