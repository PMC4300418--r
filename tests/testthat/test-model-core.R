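test_that("disease status is linear in time and guards positivity", {
  expect_equal(disease_status(0, 1.16, -1e-4), 1.16)
  expect_equal(disease_status(84, 1.16, -1e-4), 1.1516)
  expect_equal(disease_status(30, 1.0, 0), 1.0)
  expect_equal(disease_status(c(0, 10, 20), 1, -0.01), c(1, 0.9, 0.8))
  expect_error(disease_status(200, 1.16, -0.01), "non-positive")
  expect_error(disease_status(-1, 1.16, 0))
})

test_that("KPD exposure superposition matches the geometric closed form", {
  reg <- dose_regimen(50, interval = 12)
  # a dose administered at t = 0 counts unless pre-dose
  expect_equal(kpd_exposure(0, reg, kde = 1), 50)
  expect_equal(kpd_exposure(0, reg, kde = 1, pre_dose = TRUE), 0)
  # 12 h half-life: steady-state trough equals exactly one dose
  kde_half <- log(2) / 0.5
  expect_equal(kpd_exposure(28, reg, kde_half, pre_dose = TRUE), 50,
               tolerance = 1e-10)
  # explicit superposition oracle at an off-grid time
  t <- 3.2; kde <- 0.8
  doses <- seq(0, 3, by = 0.5)
  expect_equal(kpd_exposure(t, reg, kde),
               sum(50 * exp(-kde * (t - doses))), tolerance = 1e-12)
  # placebo is identically zero for all parameterisations
  plac <- dose_regimen(0)
  for (p in c("a", "b", "c"))
    expect_identical(kpd_exposure(c(0, 5, 100), plac, 1, p), c(0, 0, 0))
  # parameterisation b: dose while active; c: kde times the amount
  expect_equal(kpd_exposure(c(5, 400), reg, 1, "b"), c(50, 0))
  expect_equal(kpd_exposure(5, reg, 2, "c"), 2 * kpd_exposure(5, reg, 2, "a"))
  expect_error(kpd_exposure(1, reg, -1), "kde")
})

test_that("Emax drug effect saturates, is monotone and bounded", {
  expect_equal(drug_effect(0, 0.36, 3.1), 0)
  expect_equal(drug_effect(1e12, 0.36, 3.1), 0.36, tolerance = 1e-9)
  # published final-model values at the 50 ug dose level
  expect_equal(drug_effect(50, 0.36, 0.36 * 8.66), 0.3388707,
               tolerance = 1e-6)
  a <- seq(0, 500, by = 0.5)
  e <- drug_effect(a, 0.36, 3.1176)
  expect_true(all(diff(e) > 0))
  expect_true(all(e < 0.36))
  expect_error(drug_effect(-1, 0.36, 3))
  expect_error(drug_effect(1, 0.36, 0))
})

test_that("covariate model reproduces reference and adjusted typical values", {
  pop <- default_pop()
  ref <- apply_covariates(pop, ref_subject())
  expect_equal(ref$int_dis, 1.16)
  expect_equal(ref$emax, 0.36)
  expect_equal(ref$edk50, 8.66 * 0.36)
  # male, severe, PICS user, 180 cm
  male <- ref_subject()
  male$sex <- "male"; male$severity <- "severe"; male$pics <- "yes"
  male$height <- 180
  tv <- apply_covariates(pop, male)
  expect_equal(tv$int_dis, 1.16 * 0.82 * 0.62 * 0.92 * (180 / 170)^1.90,
               tolerance = 1e-10)
  expect_equal(tv$int_dis, 0.60481, tolerance = 1e-4)
  # severe & reversible on Emax
  sev <- ref_subject(); sev$severity <- "severe"; sev$reversibility <- "yes"
  expect_equal(apply_covariates(pop, sev)$emax, 0.36 * 0.94 * 1.05,
               tolerance = 1e-12)
  expect_error(apply_covariates(pop, ref_subject()[, -4]), "not present")
  bad <- ref_subject(); bad$height <- -1
  expect_error(apply_covariates(pop, bad), "non-positive")
})

test_that("exponential IIV acts multiplicatively and flags invalid etas", {
  typ <- list(kin = 0.116, int_dis = 1.16, slope_dis = -1e-4, emax = 0.36,
              edk50 = 3.12, kde = 1)
  id0 <- apply_iiv(typ)
  expect_equal(id0$int_dis_i, 1.16)
  expect_equal(id0$emax_i, 0.36)
  dbl <- apply_iiv(typ, c(int_dis = log(2)))
  expect_equal(dbl$int_dis_i, 2.32)
  expect_equal(dbl$emax_i, 0.36)   # untouched parameter passes through
  om <- copdjm:::as_omega(c(int_dis = 0.0625, emax = 0))
  expect_error(apply_iiv(typ, c(emax = 0.1), omega = om), "without IIV")
  expect_error(apply_iiv(typ, c(nonsense = 0.1)), "unknown")
})

test_that("empirical log-parameter SD converges to omega", {
  set.seed(421)
  n <- 1e5
  omega <- 0.25
  etas <- rnorm(n, 0, omega)
  vals <- vapply(seq_len(200), function(i)
    apply_iiv(list(int_dis = 1.16), c(int_dis = etas[i]))$int_dis_i,
    numeric(1))
  expect_equal(sd(log(vals / 1.16)), sd(etas[1:200]), tolerance = 1e-12)
  # full-sample check within 3 SE of the target omega
  se <- omega / sqrt(2 * (n - 1))
  expect_lt(abs(sd(etas) - omega), 3 * se)
  # CV% reporting convention
  expect_equal(iiv_cv(0.0625), 25)
  expect_equal(iiv_cv(0.0625, exact = TRUE), 100 * sqrt(exp(0.0625) - 1))
})

test_that("turnover solver: steady state, closed-form oracle, asymptote", {
  # placebo, zero slope: trajectory stays at Dis (turnover conservation)
  ind <- apply_iiv(list(kin = 0.116, int_dis = 1.16, slope_dis = 0,
                        emax = 0.36, edk50 = 3.12, kde = 1))
  tr <- solve_fev1(ind, dose_regimen(0), seq(0, 168, by = 28))
  expect_equal(tr$ipred, rep(1.16, 7), tolerance = 1e-12)
  tr_ode <- solve_fev1(ind, dose_regimen(0), seq(0, 168, by = 28),
                       method = "ode")
  expect_equal(tr_ode$ipred, rep(1.16, 7), tolerance = 1e-6)

  # constant-coefficient linear ODE: analytic exponential relaxation
  # (start away from steady state by switching the drug on)
  reg <- dose_regimen(50, interval = 12)
  ind2 <- apply_iiv(list(kin = 0.116, int_dis = 1.16, slope_dis = 0,
                         emax = 0.36, edk50 = 3.12, kde = 1))
  times <- c(7, 14, 28, 56, 84)
  tr2 <- solve_fev1(ind2, reg, times)
  a_tr <- kpd_exposure(times, reg, 1, pre_dose = TRUE)
  eff <- drug_effect(a_tr, 0.36, 3.12)
  k <- 0.116 / 1.16
  f_prev <- 1.16; t_prev <- 0
  for (j in seq_along(times)) {
    fin <- 1.16 * (1 + eff[j])
    f_an <- fin + (f_prev - fin) * exp(-k * (times[j] - t_prev))
    expect_equal(tr2$ipred[j], f_an, tolerance = 1e-10)
    f_prev <- f_an; t_prev <- times[j]
  }
  # long-horizon asymptote: Dis * (1 + Emax A / (EDK50 + A))
  tr3 <- solve_fev1(ind2, dose_regimen(50, 12, end_time = 4000),
                    c(2000, 3000))
  a_ss <- kpd_exposure(3000, dose_regimen(50, 12, end_time = 4000), 1,
                       pre_dose = TRUE)
  expect_equal(tr3$ipred[2], 1.16 * (1 + drug_effect(a_ss, 0.36, 3.12)),
               tolerance = 1e-6)
})

test_that("closed-form and numeric trajectories agree on random draws", {
  set.seed(2024)
  reg <- dose_regimen(50, interval = 12)
  times <- seq(0, 168, by = 28)
  for (rep in 1:100) {
    ind <- random_indiv()
    active <- runif(1) < 0.5
    r <- if (active) reg else dose_regimen(0)
    cl <- solve_fev1(ind, r, times, method = "closed")
    od <- solve_fev1(ind, r, times, method = "ode")
    expect_lt(max(abs(cl$ipred - od$ipred)), 1e-6)
  }
})

test_that("residual error models nest and reduce correctly", {
  expect_equal(residual_error(1.16, 0.13, 0, eps = 0), 1.16)
  expect_equal(residual_error(1.16, 0.13, 0, eps = 1), 1.29)
  expect_equal(residual_error(1, 0, 0.1, eps = 0.5, model = "proportional"),
               1.05)
  # combined with sigma_prop = 0 reduces to additive
  eps <- cbind(rnorm(5), rnorm(5))
  expect_equal(residual_error(rep(1.16, 5), 0.13, 0, eps, "combined"),
               residual_error(rep(1.16, 5), 0.13, 0, eps, "additive"))
  expect_error(residual_error(1, -0.1, 0, eps = 0), "sigmas")
  expect_error(residual_error(-1, 0.1, 0, eps = 0), "ipred")
})
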