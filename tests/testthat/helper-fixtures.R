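# shared fixtures: small designs and convenience constructors

ref_subject <- function() {
  data.frame(sex = "female", severity = "moderate", pics = "no",
             reversibility = "no", smoking = "no",
             height = 170, age = 65, weight = 75, bmi = 75 / 1.7^2)
}

# population without covariates / IIV / noise / dropout, for deterministic
# structural checks
bare_pop <- function(...) {
  pop_parameters(covariate_effects = list(),
                 omega = c(int_dis = 0),
                 sigma_add = 0, hazard = hazard_spec(beta0 = 0), ...)
}

small_design <- function(n = 50, seed = 1, duration = 24, visit = 4)
  trial_design(n_subjects = n, seed = seed, duration = duration,
               visit_interval = visit)

# engine representation + th for direct likelihood checks
eng_of <- function(ds) copdjm:::dataset_to_eng(ds)

# a random valid individual-parameter draw for property tests
random_indiv <- function() {
  apply_iiv(list(kin = exp(stats::runif(1, log(0.05), log(0.3))),
                 int_dis = stats::runif(1, 0.6, 1.8),
                 slope_dis = -10^stats::runif(1, -5, -3.3),
                 emax = stats::runif(1, 0.05, 0.9),
                 edk50 = stats::runif(1, 1, 10),
                 kde = exp(stats::runif(1, log(0.3), log(3)))))
}
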