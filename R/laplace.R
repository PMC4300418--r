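#' Subject data for the per-subject likelihood operations
#'
#' A light container for one subject's longitudinal and terminal records,
#' used by [individual_joint_loglik()] and [laplace_marginal_loglik()].
#'
#' @param times observation times (days), sorted, `>= 0`.
#' @param dv observed trough FEV1 (L) at `times`.
#' @param regimen a [dose_regimen()].
#' @param event `"completed"`, `"dropped"`, or `"none"` (no dropout term in
#'   the likelihood).
#' @param next_scheduled_time for dropouts, the first missed visit; for
#'   completers, the trial end (days).
#' @param covariates one-row data.frame of baseline covariates (optional).
#' @return an object of class `copd_subject`.
#' @export
subject_data <- function(times, dv, regimen = dose_regimen(0),
                         event = c("completed", "dropped", "none"),
                         next_scheduled_time = max(times),
                         covariates = NULL) {
  event <- match.arg(event)
  stopifnot(length(times) >= 1, length(dv) == length(times),
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, dv = dv, regimen = regimen, event = event,
                 next_scheduled_time = next_scheduled_time,
                 covariates = covariates),
            class = "copd_subject")
}

#' Individual joint log-likelihood
#'
#' Log-likelihood of one subject's data given fixed individual parameters
#' (no random-effect prior): the sum of Gaussian log-densities of the
#' observations around the individual prediction, plus the log of the
#' subject's dropout / completion probability (the survivor difference for
#' a dropout interval, the survivor at the trial end for a completer).
#'
#' @param subject a [subject_data()].
#' @param indiv an [apply_iiv()] result.
#' @param pop a [pop_parameters()] (residual error and hazard parameters).
#' @return log-likelihood (scalar).
#' @export
individual_joint_loglik <- function(subject, indiv, pop) {
  stopifnot(inherits(subject, "copd_subject"), inherits(indiv, "copd_indiv"))
  if (pop$sigma_add == 0 && pop$sigma_prop == 0)
    stop("residual variance is zero; the observation density is degenerate")
  tr <- solve_fev1(indiv, subject$regimen, subject$times,
                   mode = pop$drug_effect_mode,
                   parameterisation = pop$exposure_parameterisation)
  sd <- sqrt(pop$sigma_add^2 + (pop$sigma_prop * tr$ipred)^2)
  ll <- sum(stats::dnorm(subject$dv, tr$ipred, sd, log = TRUE))
  if (subject$event != "none") {
    path <- ipred_step_path(subject$times / 7, tr$ipred)
    rec <- dropout_record("s", max(subject$times) / 7,
                          subject$next_scheduled_time / 7,
                          event = if (subject$event == "dropped") "dropped"
                                  else "completed")
    ll <- ll + log(interval_dropout_probability(rec, pop$hazard, path))
  }
  ll
}

#' Laplace approximation of a marginal log-likelihood
#'
#' Generic single-subject Laplace marginalisation over random effects:
#' maximises \eqn{g(\eta) = \log p(y|\eta) + \log \phi(\eta; 0, \Omega)}
#' (inner Newton-type optimisation via `nlminb` with a finite-difference
#' Hessian at the mode) and returns
#' \eqn{g(\hat\eta) + \frac{d}{2}\log 2\pi - \frac12 \log|{-H}|}.
#' For a linear-Gaussian subject this is exact.
#'
#' @param loglik_fn function taking a named numeric eta vector and
#'   returning the conditional log-likelihood.
#' @param omega random-effect covariance matrix (named, positive definite),
#'   or a single variance for `d = 1`.
#' @param eta_init starting value.
#' @param tol convergence tolerance of the inner optimisation.
#' @return list with `logmarg`, `eta_hat`, and `neg_hessian`.
#' @export
laplace_marginal <- function(loglik_fn, omega, eta_init = NULL,
                             tol = 1e-10) {
  if (!is.matrix(omega)) omega <- matrix(omega, 1, 1)
  d <- nrow(omega)
  nm <- rownames(omega)
  if (any(diag(omega) <= 0)) stop("omega must be positive definite")
  oi <- solve(omega)
  ldo <- determinant(omega, logarithm = TRUE)$modulus
  g <- function(eta) {
    if (!is.null(nm)) names(eta) <- nm
    loglik_fn(eta) - 0.5 * drop(t(eta) %*% oi %*% eta) -
      0.5 * (d * log(2 * pi) + ldo)
  }
  if (is.null(eta_init)) eta_init <- rep(0, d)
  opt <- stats::nlminb(eta_init, function(e) -g(e),
                       control = list(rel.tol = tol, x.tol = 1e-12))
  eta_hat <- opt$par
  H <- stats::optimHess(eta_hat, function(e) -g(e))   # = -g''(eta_hat)
  ld <- determinant(H, logarithm = TRUE)
  if (ld$sign <= 0) stop("negative Hessian at the eta mode is not positive ",
                         "definite; inner optimisation did not converge")
  if (!is.null(nm)) names(eta_hat) <- nm
  list(logmarg = -opt$objective + 0.5 * d * log(2 * pi) -
         0.5 * as.numeric(ld$modulus),
       eta_hat = eta_hat, neg_hessian = H)
}

#' Laplace marginal log-likelihood of one subject
#'
#' Convenience wrapper combining [individual_joint_loglik()] with
#' [laplace_marginal()]: random effects named by `rownames(omega)` act on
#' the covariate-adjusted typical values through the exponential IIV model.
#' As `omega` shrinks to zero the marginal tends to the eta-at-zero
#' likelihood.
#'
#' @param subject a [subject_data()].
#' @param pop a [pop_parameters()].
#' @param omega named IIV covariance matrix; defaults to `pop$omega`.
#' @return list with `logmarg`, `eta_hat`, `neg_hessian`.
#' @export
laplace_marginal_loglik <- function(subject, pop, omega = pop$omega) {
  cov <- subject$covariates
  if (is.null(cov)) cov <- data.frame(row.names = 1)
  typ <- apply_covariates(pop, cov)
  nm <- rownames(omega)
  fn <- function(eta) {
    names(eta) <- nm
    indiv <- apply_iiv(typ, eta, omega = NULL)
    individual_joint_loglik(subject, indiv, pop)
  }
  laplace_marginal(fn, omega)
}
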