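#' Parameter-recovery experiment under the published final model
#'
#' Simulates one virtual trial under the published final-model parameter
#' set — 2000 subjects in two balanced arms (placebo vs 50 ug twice
#' daily), 24 weeks with visits every 4 weeks, pooled-trial covariate
#' marginals, IIV on the disease baseline and Emax — and re-estimates the
#' joint model by Laplace marginal likelihood.  `kde` and the EDK50/Emax
#' ratio are fixed at their generative values: with a single active dose
#' level Emax and EDK50 are only jointly identified, so the recovery
#' protocol estimates Emax conditional on the exposure constants.  The
#' disease slope, turnover input and covariate coefficients are likewise
#' held at the generative values; the free parameters are the disease
#' baseline, Emax, the additive residual SD, both dropout coefficients and
#' both IIV variances.
#'
#' Estimation starts from values dispersed away from the truth so the
#' returned estimates are the data's own maximum-likelihood solution.
#'
#' @param seed simulation seed.
#' @param n_subjects cohort size.
#' @param compute_se propagate to [fit_joint()].
#' @param control optimiser control, see [fit_joint()].
#' @return list with `fit` (a `copd_fit`), `pop` (the generative
#'   parameters) and `estimates`: named vector with `int_dis` (L),
#'   `sigma_add` (L), `emax`, `beta0` (1/week), `beta2` (1/L) and
#'   `iiv_int_dis_cv` (CV%).
#' @export
recovery_experiment <- function(seed = 20140918, n_subjects = 2000,
                                compute_se = FALSE, control = list()) {
  pop <- default_pop()
  design <- trial_design(n_subjects = n_subjects, seed = seed)
  ds <- simulate_trial(pop, design)
  init <- pop_parameters(
    tv_int_dis = 1.0, tv_emax = 0.5, sigma_add = 0.2,
    omega = c(int_dis = 0.04, emax = 0.25),
    hazard = hazard_spec(beta0 = 0.01, beta2 = -0.5),
    covariate_effects = pop$covariate_effects)
  fit <- fit_joint(ds, init,
                   estimate = c("tv_int_dis", "tv_emax", "sigma_add",
                                "beta0", "beta2", "omega_int_dis",
                                "omega_emax"),
                   iiv_on = c("int_dis", "emax"),
                   compute_se = compute_se, control = control)
  cf <- coef(fit)
  list(fit = fit, pop = pop,
       estimates = c(int_dis = unname(cf["tv_int_dis"]),
                     sigma_add = unname(cf["sigma_add"]),
                     emax = unname(cf["tv_emax"]),
                     beta0 = unname(cf["beta0"]),
                     beta2 = unname(cf["beta2"]),
                     iiv_int_dis_cv = iiv_cv(unname(cf["omega_int_dis"]))))
}
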