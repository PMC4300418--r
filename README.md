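# copdjm — joint modelling of FEV1 progression, bronchodilator response and dropout in COPD trials

Clinical trials in chronic obstructive pulmonary disease (COPD) read
efficacy from trough FEV1, an endpoint that drifts with disease
progression, responds slowly to bronchodilators, and is censored by
study discontinuation that is anything but random: patients whose lung
function deteriorates leave first.  Analysing the longitudinal endpoint
alone therefore overstates the surviving cohort and distorts the
drug-effect estimate.  `copdjm` is an R package for trialists and
pharmacometricians who want to simulate and estimate all three processes
in one model.

## The model

Trough FEV1 follows an indirect-response (turnover) model

    dFEV1/dt = Kin − Kout(t) · FEV1,      Kout(t) = Kin / Dis(t),

where the disease status `Dis(t) = Int_Dis + Slope_Dis·t` (the ratio
Kin/Kout, i.e. the drug-free steady state) declines linearly.  Because
inhaled bronchodilators lack plasma pharmacokinetics, drug exposure `A` is
kinetic-pharmacodynamic (KPD): a virtual compartment driven by dose with
first-order loss `KDE`.  The effect is an Emax function acting
multiplicatively on the input,

    Kin · (1 + Emax·A / (EDK50 + A)),

with `EDK50` parameterised as a ratio to `Emax` (one active dose level
makes them jointly weakly identified; an optional normal/inverse-Wishart
prior penalty carries historical information).  Dropout is a time-to-event
process with hazard

    h(t) = β0 · exp(β1·FEV1 + β2·IPRED)     [per week],

whose dependence on the *model-predicted* FEV1 (β2 < 0) makes missingness
informative, so the longitudinal and dropout likelihoods are maximised
jointly, with lognormal inter-individual variability integrated out by the
Laplace approximation.  Covariates (sex, height, disease severity,
reversibility, prior inhaled corticosteroid use) enter as power or
multiplicative effects.

The package provides a virtual-trial generator with the pooled Phase II
covariate marginals, the joint Laplace estimator, stepwise covariate
modelling (forward 3.84 / backward 11 on the objective function), a
case-resampling bootstrap, and simulation diagnostics: dropout-aware
visual predictive checks, Kaplan–Meier overlays and normalised prediction
distribution errors.

## Worked example

Simulate a 300-subject, 24-week placebo-controlled trial under the
final-model parameters and re-estimate the model:

```r
library(copdjm)

pop <- default_pop()                         # published final-model values
des <- trial_design(n_subjects = 300, seed = 7)
ds  <- simulate_trial(pop, des)

mean(dropout_records(ds)$event == "dropped")
#> [1] 0.07333333

fit <- fit_joint(ds, pop, compute_se = FALSE)
fit
#> Joint Laplace fit: 300 subjects, 2020 observations, MOFV -1333.411 (converged)
#>      parameter estimate se
#>     tv_int_dis  1.15800 NA
#>        tv_emax  0.35600 NA
#>      sigma_add  0.12920 NA
#>          beta0  0.01275 NA
#>          beta2 -1.80800 NA
#>  omega_int_dis  0.05789 NA
#>     omega_emax  0.39100 NA
#> eta shrinkage (%): int_dis 8.7, emax 48.5
```

The disease baseline (1.158 L vs 1.16 generative), Emax (0.356 vs 0.36)
and residual SD (0.129 vs 0.13 L) recover closely; the dropout
coefficients are the least determined quantities — 300 subjects yield only
~20 discontinuations, so `beta0` and `beta2` scatter widely around their
generative values (0.006 and −0.88) until the cohort grows.  Diagnostics:

```r
v <- vpc(ds, fit$pop, des, n_sim = 200, strata = "arm", seed = 1)
plot(v)                       # percentile bands vs observed percentiles
npde(ds, fit$pop, des, K = 1000, seed = 2)
#> NPDE over 2020 observations: mean -0.0041, variance 1.0293, KS D 0.0155 (p 0.718)
```

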