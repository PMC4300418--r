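#' Disease status over time
#'
#' Linear disease progression of the steady-state trough FEV1,
#' \eqn{Dis(t) = Int\_Dis + Slope\_Dis \cdot t}.  A negative slope encodes
#' decline.  Disease status is the ratio \eqn{K_{in}/K_{out}} and must stay
#' positive over the evaluated horizon.
#'
#' @param t time (days), vectorised, `>= 0`.
#' @param int_dis disease baseline intercept (L), > 0.
#' @param slope_dis disease slope (L/day).
#' @return disease status (L), same length as `t`.
#' @export
#' @examples
#' disease_status(c(0, 84), 1.16, -1e-4)
disease_status <- function(t, int_dis, slope_dis) {
  stopifnot(all(t >= 0), int_dis > 0)
  dis <- int_dis + slope_dis * t
  if (any(dis <= 0))
    stop("disease status became non-positive within the evaluated horizon")
  dis
}

#' KPD exposure variable
#'
#' Dose-driven exposure of the kinetic-pharmacodynamic model.  Plasma
#' pharmacokinetics are unavailable for inhaled bronchodilators, so exposure
#' is represented by a virtual compartment: parameterisation `"a"` is the
#' amount, the multi-dose superposition of first-order decay
#' \eqn{Dose\, e^{-KDE\,\Delta t}} over all administered doses; `"b"` is the
#' dose itself, constant while dosing is active; `"c"` is the input rate,
#' `kde` times the superposed decaying amount.
#'
#' With `pre_dose = TRUE` a dose administered exactly at `t` is not counted,
#' giving the trough exposure at a scheduled (pre-dose) visit.
#'
#' @param t evaluation times (days), vectorised.
#' @param regimen a [dose_regimen()].
#' @param kde elimination rate constant (1/day), > 0.
#' @param parameterisation `"a"`, `"b"` or `"c"`.
#' @param pre_dose exclude a dose given exactly at `t`.
#' @return exposure (ug), same length as `t`.
#' @export
#' @examples
#' reg <- dose_regimen(50, interval = 12)
#' kpd_exposure(0, reg, kde = 1)                     # dose just given: 50
#' kpd_exposure(28, reg, kde = 1, pre_dose = TRUE)   # steady-state trough
kpd_exposure <- function(t, regimen, kde,
                         parameterisation = c("a", "b", "c"),
                         pre_dose = FALSE) {
  parameterisation <- match.arg(parameterisation)
  stopifnot(inherits(regimen, "copd_regimen"))
  if (!is.finite(kde) || kde <= 0) stop("kde must be > 0")
  dose <- regimen$dose_amount
  if (dose == 0) return(rep(0, length(t)))
  tau <- regimen$interval / 24          # hours -> days
  if (parameterisation == "b") {
    return(ifelse(t >= regimen$start_time & t <= regimen$end_time, dose, 0))
  }
  rel <- t - regimen$start_time
  n_given <- floor(rel / tau) + 1        # doses at start + k*tau, k >= 0
  on_grid <- abs(rel / tau - round(rel / tau)) < 1e-9
  if (pre_dose) n_given <- ifelse(on_grid, round(rel / tau), n_given)
  n_max <- floor((regimen$end_time - regimen$start_time) / tau) + 1
  m <- pmin(pmax(n_given, 0), n_max)
  # time since most recent counted dose; geometric superposition in a
  # numerically safe form (no growing exponentials)
  delta <- rel - (m - 1) * tau
  a <- ifelse(m >= 1,
              dose * exp(-kde * delta) *
                (1 - exp(-kde * m * tau)) / (1 - exp(-kde * tau)),
              0)
  a[t < regimen$start_time] <- 0
  if (parameterisation == "c") a <- kde * a
  a
}

#' Emax drug effect
#'
#' Fractional bronchodilator effect \eqn{E_{max} A/(EDK_{50} + A)} of the
#' KPD exposure `a`.  The caller applies the value per mode; in the final
#' model it multiplies the turnover input as \eqn{K_{in}(1 + E)}.
#'
#' @param a exposure (ug), `>= 0`, vectorised.
#' @param emax maximum fractional effect, `>= 0`.
#' @param edk50 exposure at half-maximal effect (ug), > 0.
#' @return effect, in `[0, emax)`.
#' @export
drug_effect <- function(a, emax, edk50) {
  if (any(a < 0)) stop("exposure must be non-negative")
  if (edk50 <= 0) stop("edk50 must be > 0")
  if (emax < 0) stop("emax must be >= 0")
  emax * a / (edk50 + a)
}

# TRUE where a covariate value is in the non-reference category
nonreference <- function(values) {
  if (is.character(values) || is.factor(values)) {
    as.character(values) %in% c("male", "severe", "yes", "1", "TRUE",
                                "smoker", "reversible")
  } else {
    as.numeric(values) != 0
  }
}

# per-subject multiplicative covariate adjustment for one parameter
# cov_df: data.frame of covariates; returns a list of multiplier vectors
# keyed by parameter name (parameters without effects are absent)
covariate_multipliers <- function(effects, cov_df) {
  out <- list()
  for (ce in effects) {
    v <- cov_df[[ce$covariate]]
    if (is.null(v))
      stop("covariate '", ce$covariate, "' not present in covariate data")
    if (anyNA(v)) stop("missing values in covariate '", ce$covariate, "'")
    m <- if (ce$kind == "power") {
      if (any(v <= 0))
        stop("non-positive value of continuous covariate '", ce$covariate, "'")
      (v / ce$reference)^ce$theta
    } else {
      ifelse(nonreference(v), ce$theta, 1)
    }
    out[[ce$parameter]] <- if (is.null(out[[ce$parameter]])) m
                           else out[[ce$parameter]] * m
  }
  out
}

#' Covariate-adjusted typical parameter values
#'
#' Applies the population's covariate model to one or more subjects.
#' Continuous covariates enter as \eqn{(x/x_{ref})^\theta}; categorical
#' covariates multiply by \eqn{\theta} in the non-reference category;
#' several effects on the same parameter multiply.  EDK50 is derived from
#' the covariate-adjusted typical Emax via the estimated ratio.
#'
#' @param pop a [pop_parameters()] object.
#' @param cov a data.frame (or coercible list) of covariates, one row per
#'   subject.
#' @return a data.frame of typical values with columns `kin`, `int_dis`,
#'   `slope_dis`, `emax`, `edk50`, `kde`.
#' @export
#' @examples
#' pop <- default_pop()
#' ref <- data.frame(sex = "female", severity = "moderate", pics = "no",
#'                   reversibility = "no", height = 170)
#' apply_covariates(pop, ref)$int_dis   # raw typical value 1.16
apply_covariates <- function(pop, cov) {
  stopifnot(inherits(pop, "copd_pop"))
  cov <- as.data.frame(cov)
  n <- nrow(cov)
  mult <- covariate_multipliers(pop$covariate_effects, cov)
  one <- rep(1, n)
  g <- function(p) if (is.null(mult[[p]])) one else mult[[p]]
  emax <- pop$tv_emax * g("emax")
  data.frame(
    kin = pop$tv_kin * g("kin"),
    int_dis = pop$tv_int_dis * g("int_dis"),
    slope_dis = pop$tv_slope_dis * g("slope_dis"),
    emax = emax,
    edk50 = pop$ratio_edk50_emax * emax,
    kde = pop$kde * g("kde")
  )
}

#' Individual parameters from typical values and random effects
#'
#' Exponential inter-individual variability: \eqn{P_i = TVP\, e^{\eta_i}}
#' for every parameter named in `etas`; parameters without IIV pass through
#' unchanged.  Supplying an eta for a parameter with zero variance in
#' `omega` is an error (it would silently have no generative counterpart).
#'
#' @param typical named list/one-row data.frame of typical values (as from
#'   [apply_covariates()]).
#' @param etas named numeric vector of random-effect deviations.
#' @param omega IIV covariance matrix (named); used to check that every eta
#'   corresponds to a parameter carrying IIV.  `NULL` skips the check.
#' @return a list of class `copd_indiv` with fields `kin_i`, `int_dis_i`,
#'   `slope_dis_i`, `emax_i`, `edk50_i`, `kde_i` and `etas`.
#' @export
apply_iiv <- function(typical, etas = numeric(0), omega = NULL) {
  typical <- as.list(typical)
  if (length(etas)) {
    if (is.null(names(etas)) || any(!nzchar(names(etas))))
      stop("etas must be named by parameter")
    if (!is.null(omega)) {
      bad <- setdiff(names(etas), rownames(omega))
      v <- diag(omega)[intersect(names(etas), rownames(omega))]
      bad <- c(bad, names(v)[v == 0])
      if (length(bad))
        stop("eta supplied for parameter(s) without IIV: ",
             paste(unique(bad), collapse = ", "))
    }
    unknown <- setdiff(names(etas), names(typical))
    if (length(unknown))
      stop("eta for unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  f <- function(p) {
    v <- typical[[p]]
    if (p %in% names(etas)) v * exp(etas[[p]]) else v
  }
  structure(list(kin_i = f("kin"), int_dis_i = f("int_dis"),
                 slope_dis_i = f("slope_dis"), emax_i = f("emax"),
                 edk50_i = f("edk50"), kde_i = f("kde"), etas = etas),
            class = "copd_indiv")
}

# one closed-form step of the turnover ODE over [t0, t1]:
#   dF/dt = kin_eff - (kout_coef / Dis(t)) * F,   Dis(t) = d0 + b (t - t0)
step_turnover <- function(f0, d0, d1, dt, b, kin_eff, kout_coef) {
  if (abs(b) < 1e-14) {
    k <- kout_coef / d0
    fin <- kin_eff / k
    fin + (f0 - fin) * exp(-k * dt)
  } else {
    r <- d1 / d0
    rp <- exp(-(kout_coef / b) * log(r))
    f0 * rp + kin_eff * d0 * (r - rp) / (kout_coef + b)
  }
}

#' Solve the individual FEV1 trajectory
#'
#' Integrates the turnover model
#' \eqn{dFEV_1/dt = K_{in}(t) - K_{out}(t) FEV_1} with
#' \eqn{K_{out}(t) = K_{in}/Dis(t)} and the Emax drug effect applied per
#' `mode`, initialised at the pre-treatment steady state
#' \eqn{FEV_1(0) = Dis(0)}.  The drug effect is held constant within each
#' interval between requested times, evaluated at the trough (pre-dose)
#' exposure of the interval's right endpoint; disease status is linear.
#' Under this piecewise structure the ODE has a closed-form solution
#' (`method = "closed"`); `method = "ode"` integrates the same piecewise
#' system numerically with `deSolve::lsoda` and is the cross-checking
#' fallback.  The additive-on-Kout mode has no closed form and always uses
#' the integrator.
#'
#' @param indiv a [apply_iiv()] result (class `copd_indiv`).
#' @param regimen a [dose_regimen()].
#' @param times sorted non-negative observation times (days).
#' @param mode drug-effect placement; see [pop_parameters()].
#' @param parameterisation KPD exposure parameterisation, see
#'   [kpd_exposure()].
#' @param method `"closed"`, `"ode"`, or `"auto"` (closed form where it
#'   exists).
#' @return a data.frame with columns `time`, `dis`, `exposure`, `kout`,
#'   `ipred`.
#' @export
solve_fev1 <- function(indiv, regimen, times,
                       mode = c("multiplicative_kin", "additive_kin",
                                "multiplicative_kout", "additive_kout"),
                       parameterisation = c("a", "b", "c"),
                       method = c("auto", "closed", "ode")) {
  mode <- match.arg(mode)
  parameterisation <- match.arg(parameterisation)
  method <- match.arg(method)
  stopifnot(inherits(indiv, "copd_indiv"))
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("times must be strictly increasing and >= 0")
  if (method == "auto")
    method <- if (mode == "additive_kout") "ode" else "closed"
  if (method == "closed" && mode == "additive_kout")
    stop("additive_kout has no closed-form solution; use method = 'ode'")

  tt <- if (times[1] > 0) c(0, times) else times
  kin <- indiv$kin_i; b <- indiv$slope_dis_i
  dis <- disease_status(tt, indiv$int_dis_i, b)
  if (regimen$dose_amount > 0) {
    a <- kpd_exposure(tt, regimen, indiv$kde_i, parameterisation,
                      pre_dose = TRUE)
  } else a <- rep(0, length(tt))
  eff <- drug_effect(a, indiv$emax_i, indiv$edk50_i)

  # per-interval coefficients (effect held at the right endpoint's trough)
  coefs <- function(e) switch(mode,
    multiplicative_kin = list(kin_eff = kin * (1 + e), kout_coef = kin),
    additive_kin       = list(kin_eff = kin + e,       kout_coef = kin),
    multiplicative_kout = list(kin_eff = kin, kout_coef = kin * (1 + e)),
    additive_kout      = list(kin_eff = kin, kout_coef = NA))

  f <- numeric(length(tt))
  f[1] <- dis[1]
  for (j in seq_len(length(tt) - 1L)) {
    cf <- coefs(eff[j + 1L])
    if (method == "closed") {
      f[j + 1L] <- step_turnover(f[j], dis[j], dis[j + 1L],
                                 tt[j + 1L] - tt[j], b,
                                 cf$kin_eff, cf$kout_coef)
    } else {
      e <- eff[j + 1L]
      rhs <- function(t, y, parms) {
        d <- indiv$int_dis_i + b * t
        kout <- switch(mode,
          multiplicative_kin = kin / d,
          additive_kin = kin / d,
          multiplicative_kout = kin * (1 + e) / d,
          additive_kout = kin / d + e)
        kin_t <- switch(mode,
          multiplicative_kin = kin * (1 + e),
          additive_kin = kin + e,
          kin)
        list(kin_t - kout * y)
      }
      sol <- deSolve::lsoda(c(F = f[j]), c(tt[j], tt[j + 1L]), rhs,
                            rtol = 1e-10, atol = 1e-12)
      if (attr(sol, "istate")[1] < 0)
        stop("ODE integrator failed between t = ", tt[j], " and ", tt[j + 1L])
      f[j + 1L] <- sol[nrow(sol), "F"]
    }
  }
  keep <- tt %in% times
  data.frame(time = tt[keep], dis = dis[keep], exposure = a[keep],
             kout = (kin / dis)[keep], ipred = f[keep])
}

#' Residual error model
#'
#' Maps a noise-free prediction and standard-normal draws to observed FEV1:
#' additive \eqn{Y = IPRED + \epsilon_{add}}, proportional
#' \eqn{Y = IPRED(1 + \epsilon_{prop})}, or combined.  The final model uses
#' the additive form.
#'
#' @param ipred noise-free predictions (L), `>= 0`.
#' @param sigma_add additive residual SD (L).
#' @param sigma_prop proportional residual SD (fraction).
#' @param eps standard-normal draws; for the combined model a two-column
#'   matrix (additive, proportional) or a single vector reused for both.
#' @param model `"additive"`, `"proportional"`, or `"combined"`.
#' @return observed values, same length as `ipred`.
#' @export
residual_error <- function(ipred, sigma_add = 0.13, sigma_prop = 0, eps,
                           model = c("additive", "proportional", "combined")) {
  model <- match.arg(model)
  if (sigma_add < 0 || sigma_prop < 0) stop("sigmas must be >= 0")
  if (any(ipred < 0)) stop("ipred must be >= 0")
  e <- unname(if (is.matrix(eps)) eps else cbind(eps, eps))
  switch(model,
    additive = ipred + sigma_add * e[, 1],
    proportional = ipred * (1 + sigma_prop * e[, 2]),
    combined = ipred * (1 + sigma_prop * e[, 2]) + sigma_add * e[, 1])
}
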