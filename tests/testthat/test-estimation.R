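test_that("individual joint log-likelihood: Gaussian and dropout pieces", {
  pop <- pop_parameters(covariate_effects = list(), sigma_add = 0.13,
                        hazard = hazard_spec(beta0 = 0.006, beta2 = -0.88))
  typ <- apply_covariates(pop, data.frame(row.names = 1))
  indiv <- apply_iiv(typ)
  # one observation equal to IPRED at t = 0, no dropout term
  s1 <- subject_data(0, indiv$int_dis_i, event = "none")
  expect_equal(individual_joint_loglik(s1, indiv, pop),
               -0.5 * log(2 * pi * 0.13^2), tolerance = 1e-12)
  # doubling sigma with a zero residual costs exactly log(2)
  pop2 <- pop_parameters(covariate_effects = list(), sigma_add = 0.26,
                         hazard = hazard_spec(beta0 = 0.006, beta2 = -0.88))
  expect_equal(individual_joint_loglik(s1, indiv, pop) -
                 individual_joint_loglik(s1, indiv, pop2),
               log(2), tolerance = 1e-12)
  # completer contribution is log S(end)
  times <- seq(0, 168, by = 28)
  tr <- solve_fev1(indiv, dose_regimen(0), times)
  s2 <- subject_data(times, tr$ipred, event = "completed")
  path <- ipred_step_path(times / 7, tr$ipred)
  ll_obs <- sum(dnorm(0, 0, 0.13, log = TRUE)) * 7
  expect_equal(individual_joint_loglik(s2, indiv, pop),
               ll_obs + log(survivor(24, pop$hazard, path)),
               tolerance = 1e-10)
  # zero residual variance is rejected
  pop0 <- pop_parameters(covariate_effects = list(), sigma_add = 0,
                         sigma_prop = 0)
  expect_error(individual_joint_loglik(s1, indiv, pop0), "degenerate")
})

test_that("Laplace is exact on the linear-Gaussian toy model", {
  # y = eta + eps, one observation y = 1, omega^2 = sigma^2 = 1:
  # -2 logL = log(4*pi) + 0.5 = 3.031024
  ll <- function(eta) dnorm(1, eta, 1, log = TRUE)
  lap <- laplace_marginal(ll, omega = 1)
  expect_equal(-2 * lap$logmarg, log(4 * pi) + 0.5, tolerance = 1e-6)
  expect_equal(lap$eta_hat, 0.5, tolerance = 1e-6, ignore_attr = TRUE)
  # exact multivariate check: 2 observations, d = 1
  y <- c(0.3, -0.2); s2 <- 0.5^2; o2 <- 0.8^2
  ll2 <- function(eta) sum(dnorm(y, eta, 0.5, log = TRUE))
  # closed form: y ~ N(0, s2 I + o2 J)
  S <- diag(s2, 2) + o2
  exact <- -0.5 * (2 * log(2 * pi) + determinant(S)$modulus +
                     drop(t(y) %*% solve(S) %*% y))
  expect_equal(laplace_marginal(ll2, o2)$logmarg, as.numeric(exact),
               tolerance = 1e-8)
})

test_that("omega -> 0 recovers the eta-at-zero likelihood", {
  ll <- function(eta) dnorm(1.1, 0.9 * exp(eta), 0.2, log = TRUE)
  l0 <- ll(0)
  expect_equal(laplace_marginal(ll, 1e-12)$logmarg, l0, tolerance = 1e-4)
})

test_that("Laplace tracks a quadrature oracle on a nonlinear subject", {
  # nonlinear 1-eta subject: lognormal baseline, two observations (a
  # moderately informative subject keeps the fixed 64-point rule itself
  # accurate; very sharp posteriors would need an adaptive rule)
  set.seed(31)
  y <- 1.16 * exp(0.3) + rnorm(2, 0, 0.25)
  ll <- function(eta) sum(dnorm(y, 1.16 * exp(eta), 0.25, log = TRUE))
  lap <- laplace_marginal(ll, omega = 0.0625)
  # 64-point Gauss-Hermite quadrature oracle
  gh <- function(nq) {
    k <- seq_len(nq)
    # nodes/weights via the Golub-Welsch eigen decomposition
    a <- rep(0, nq); b <- sqrt(k[-nq] / 2)
    Jm <- diag(a); Jm[cbind(k[-nq], k[-nq] + 1)] <- b
    Jm[cbind(k[-nq] + 1, k[-nq])] <- b
    e <- eigen(Jm, symmetric = TRUE)
    x <- e$values; w <- sqrt(pi) * e$vectors[1, ]^2
    s <- sqrt(2 * 0.0625)
    log(sum(w * exp(vapply(s * x, ll, numeric(1)))) / sqrt(pi))
  }
  expect_lt(abs(-2 * lap$logmarg - (-2 * gh(64))), 0.1)
})

test_that("batched and generic Laplace marginals agree on trial data", {
  pop <- default_pop()
  ds <- simulate_trial(pop, small_design(n = 25, seed = 11))
  dat <- eng_of(ds)
  th <- copdjm:::pop_to_th(pop, dat)
  om2 <- c(int_dis = 0.0625, emax = 0.49)
  lb <- copdjm:::laplace_batch(dat, th, om2)
  for (i in c(1, 5, 12, 25)) {
    oj <- which(dat$obs[i, ])
    reg <- if (dat$active[i]) dat$regimen else dose_regimen(0)
    dropped <- !is.na(dat$drop_m[i])
    subj <- subject_data(
      dat$times[oj], dat$y[i, oj], reg,
      event = if (dropped) "dropped" else "completed",
      next_scheduled_time = if (dropped) dat$times[dat$drop_m[i] + 1L]
        else max(dat$times),
      covariates = dat$cov_df[i, ])
    gen <- laplace_marginal_loglik(subj, pop, copdjm:::as_omega(om2))
    expect_equal(lb$marginal[i], gen$logmarg, tolerance = 1e-4)
  }
})

test_that("prior penalty: minimum at the mean, Mahalanobis differences", {
  pr <- prior_spec()
  th_mean <- pr$theta_means
  p0 <- prior_penalty(th_mean, prior = pr)
  expect_equal(p0, 0)
  # any displacement raises the penalty
  th1 <- th_mean + c(0.1, 0)
  expect_gt(prior_penalty(th1, prior = pr), p0)
  # penalty difference equals the Mahalanobis quadratic-form difference
  th2 <- th_mean + c(-0.05, 0.3)
  Si <- solve(pr$theta_cov)
  q <- function(th) drop(t(th - th_mean) %*% Si %*% (th - th_mean))
  expect_equal(prior_penalty(th1, prior = pr) -
                 prior_penalty(th2, prior = pr),
               q(th1) - q(th2), tolerance = 1e-10)
  expect_equal(pr$df, 24)
  # inverse-Wishart part peaks near the prior scale
  om_names <- rownames(pr$omega_scale)
  mk <- function(s) {
    m <- s * pr$omega_scale
    dimnames(m) <- dimnames(pr$omega_scale)
    m
  }
  pen_at <- function(s) prior_penalty(th_mean, mk(s), pr)
  expect_lt(pen_at(1), pen_at(4))
  expect_lt(pen_at(1), pen_at(0.25))
})

test_that("placebo-only data with the prior pulls Emax to the prior mean", {
  pop <- pop_parameters(covariate_effects = list(),
                        omega = c(int_dis = 0.0625),
                        hazard = hazard_spec(beta0 = 0.004, beta2 = 0))
  ds <- simulate_trial(pop, trial_design(
    n_subjects = 60, seed = 17, arms = list(placebo = dose_regimen(0)),
    allocation = 1, duration = 12))
  pr <- prior_spec(theta_means = c(tv_emax = 0.78),
                   theta_cov = matrix(0.04, 1, 1,
                                      dimnames = list("tv_emax", "tv_emax")),
                   omega_scale = NULL)
  f <- fit_joint(ds, pop, estimate = c("tv_int_dis", "tv_emax", "sigma_add",
                                       "omega_int_dis"),
                 iiv_on = "int_dis", prior = pr, compute_se = FALSE)
  expect_equal(unname(coef(f)["tv_emax"]), 0.78, tolerance = 1e-3)
})

test_that("descent property and invariance to data permutation", {
  pop <- default_pop()
  ds <- simulate_trial(pop, small_design(n = 60, seed = 13))
  f <- fit_joint(ds, pop, compute_se = FALSE,
                 control = list(iter.max = 60))
  dat <- eng_of(ds)
  th <- copdjm:::pop_to_th(pop, dat)
  m0 <- -2 * sum(copdjm:::laplace_batch(
    dat, th, c(int_dis = 0.0625, emax = 0.49))$marginal)
  expect_lte(f$mofv, m0)
  # permuting subjects leaves the MOFV unchanged
  ids <- unique(ds$ID)
  perm <- setNames(sample(ids), ids)
  ds2 <- ds
  ds2$ID <- perm[as.character(ds$ID)]
  ds2 <- ds2[order(ds2$ID, ds2$TIME, ds2$EVID), ]
  class(ds2) <- class(ds)
  th2 <- copdjm:::pop_to_th(pop, eng_of(ds2))
  m0p <- -2 * sum(copdjm:::laplace_batch(
    eng_of(ds2), th2, c(int_dis = 0.0625, emax = 0.49))$marginal)
  expect_equal(m0p, m0, tolerance = 1e-6)
})

test_that("estimates are invariant to dispersed starting points", {
  # a small recovery set with plentiful dropout events so every parameter,
  # including the hazard coefficients, is well conditioned.  The
  # finite-difference Laplace machinery bounds the reproducible precision
  # of the flat beta0/beta2 ridge at roughly 1%; the longitudinal
  # parameters reproduce much more tightly.
  gen <- pop_parameters(covariate_effects = default_pop()$covariate_effects,
                        omega = c(int_dis = 0.0625, emax = 0.49),
                        hazard = hazard_spec(beta0 = 0.05, beta2 = -0.88))
  ds <- simulate_trial(gen, trial_design(n_subjects = 150, seed = 19))
  starts <- list(
    gen,
    pop_parameters(tv_int_dis = 0.8, tv_emax = 0.6, sigma_add = 0.25,
                   omega = c(int_dis = 0.09, emax = 0.2),
                   hazard = hazard_spec(beta0 = 0.1, beta2 = -0.2),
                   covariate_effects = gen$covariate_effects),
    pop_parameters(tv_int_dis = 1.6, tv_emax = 0.15, sigma_add = 0.08,
                   omega = c(int_dis = 0.03, emax = 1),
                   hazard = hazard_spec(beta0 = 0.01, beta2 = -1.5),
                   covariate_effects = gen$covariate_effects))
  fits <- lapply(starts, function(p0)
    fit_joint(ds, p0, compute_se = FALSE, control = list(iter.max = 300)))
  ref <- coef(fits[[1]])
  long_pars <- c("tv_int_dis", "tv_emax", "sigma_add", "omega_int_dis",
                 "omega_emax")
  for (f in fits[-1]) {
    expect_equal(coef(f)[long_pars], ref[long_pars], tolerance = 2e-3)
    expect_equal(coef(f), ref, tolerance = 0.02)
  }
})

test_that("fit serialises to structured JSON with provenance", {
  pop <- default_pop()
  ds <- simulate_trial(pop, small_design(n = 40, seed = 23))
  f <- fit_joint(ds, pop, compute_se = FALSE,
                 control = list(iter.max = 40))
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$estimates$tv_int_dis, coef(f)[["tv_int_dis"]])
  expect_true(js$settings$include_dropout)
  expect_equal(js$n_subjects, 40)
})
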