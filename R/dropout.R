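#' Piecewise-constant predicted-FEV1 path
#'
#' Dropout hazards depend on the individual-predicted FEV1, which is only
#' materialised at visit times; between visits it is held constant at the
#' value of the most recent visit (left-continuous step function).
#'
#' @param times step breakpoints (weeks), starting at 0, strictly
#'   increasing.
#' @param values predicted FEV1 (L) on each interval `[times[j],
#'   times[j+1])`; the last value extends beyond the last breakpoint.
#' @return a function of time (weeks) with class `copd_step_path`.
#' @export
ipred_step_path <- function(times, values) {
  stopifnot(length(times) == length(values), times[1] == 0,
            !is.unsorted(times, strictly = TRUE))
  f <- function(t) values[findInterval(t, times, left.open = FALSE)]
  structure(f, class = c("copd_step_path", "function"),
            times = times, values = values)
}

# constant path convenience (used widely in tests/examples)
constant_path <- function(value) ipred_step_path(0, value)

#' Dropout hazard
#'
#' \eqn{h(t) = base(t) \exp(\beta_1 FEV_1 + \beta_2 IPRED)} with `base(t)`
#' determined by the hazard form; see [hazard_spec()].  The "exponential"
#' form is Gompertz, \eqn{\beta_0 e^{shape \cdot t}}; Weibull with
#' `shape = 1` reduces to the constant form.
#'
#' @param t time (weeks), `>= 0`, vectorised.
#' @param spec a [hazard_spec()].
#' @param fev1_obs observed FEV1 (L); required only when `beta1 != 0`.
#' @param ipred individual-predicted FEV1 (L), `>= 0`.
#' @return hazard (1/week).
#' @export
#' @examples
#' hazard(0, hazard_spec(beta0 = 0.006, beta2 = 0), ipred = 1)    # 0.006
hazard <- function(t, spec, fev1_obs = NULL, ipred) {
  stopifnot(inherits(spec, "copd_hazard"))
  if (any(t < 0)) stop("t must be >= 0")
  if (any(ipred < 0)) stop("ipred must be >= 0")
  lin <- spec$beta2 * ipred
  if (spec$beta1 != 0) {
    if (is.null(fev1_obs))
      stop("fev1_obs is required when beta1 != 0")
    lin <- lin + spec$beta1 * fev1_obs
  }
  base <- switch(spec$form,
    constant = rep(spec$beta0, length(t)),
    exponential = spec$beta0 * exp(spec$shape * t),
    weibull = spec$beta0 * spec$shape * t^(spec$shape - 1))
  base * exp(lin)
}

# integral of the baseline hazard over [a, b] (closed forms)
base_cumhaz <- function(spec, a, b) {
  switch(spec$form,
    constant = spec$beta0 * (b - a),
    exponential = spec$beta0 / spec$shape *
      (exp(spec$shape * b) - exp(spec$shape * a)),
    weibull = spec$beta0 * (b^spec$shape - a^spec$shape))
}

#' Cumulative dropout hazard
#'
#' \eqn{\int_{t_0}^{t_1} h(s)\,ds}.  When the predicted-FEV1 path is a
#' [ipred_step_path()], the integral is evaluated exactly segment by
#' segment (the baseline-hazard integral has a closed form for all three
#' forms); for an arbitrary path, adaptive quadrature
#' (`stats::integrate`) is used.
#'
#' @param t0,t1 integration bounds (weeks), `t1 >= t0 >= 0`.
#' @param spec a [hazard_spec()].
#' @param ipred_path function of time (weeks) returning predicted FEV1 (L).
#' @return cumulative hazard (dimensionless).
#' @export
cumulative_hazard <- function(t0, t1, spec, ipred_path) {
  stopifnot(t1 >= t0, t0 >= 0)
  if (spec$beta1 != 0)
    stop("cumulative hazard over an observed-FEV1 term (beta1 != 0) is not ",
         "defined between visits; use the interval likelihood instead")
  if (t1 == t0) return(0)
  if (inherits(ipred_path, "copd_step_path")) {
    times <- attr(ipred_path, "times"); values <- attr(ipred_path, "values")
    cuts <- sort(unique(c(t0, t1, times[times > t0 & times < t1])))
    lo <- cuts[-length(cuts)]; hi <- cuts[-1]
    sum(base_cumhaz(spec, lo, hi) * exp(spec$beta2 * ipred_path(lo)))
  } else {
    f <- function(s) hazard(s, spec, ipred = ipred_path(s))
    q <- stats::integrate(Vectorize(f), t0, t1, rel.tol = 1e-10,
                          abs.tol = 1e-12, subdivisions = 500L)
    if (q$message != "OK") stop("quadrature failed: ", q$message)
    q$value
  }
}

#' Survivor function of dropout
#'
#' Probability of remaining in the trial beyond `t`,
#' \eqn{S(t) = \exp(-\int_0^t h)}.
#'
#' @inheritParams cumulative_hazard
#' @param t time (weeks), vectorised.
#' @return probability in `[0, 1]`, non-increasing in `t`.
#' @export
survivor <- function(t, spec, ipred_path) {
  vapply(t, function(ti) exp(-cumulative_hazard(0, ti, spec, ipred_path)),
         numeric(1))
}

#' Dropout probability density
#'
#' \eqn{pdf(t) = S(t)\,h(t)}; integrates to \eqn{1 - S(\infty)} over
#' \eqn{[0, \infty)}.
#'
#' @inheritParams survivor
#' @return density (1/week).
#' @export
dropout_pdf <- function(t, spec, ipred_path) {
  survivor(t, spec, ipred_path) * hazard(t, spec, ipred = ipred_path(t))
}

#' Dropout/completion record
#'
#' @param subject_id identifier.
#' @param last_observed_time last visit with an observation (weeks).
#' @param next_scheduled_time for dropouts, the first scheduled visit after
#'   the event; for completers, the trial end time.
#' @param event `"dropped"` or `"completed"`.
#' @return an object of class `copd_dropout_record`.
#' @export
dropout_record <- function(subject_id, last_observed_time,
                           next_scheduled_time,
                           event = c("dropped", "completed")) {
  event <- match.arg(event)
  if (event == "dropped" && next_scheduled_time <= last_observed_time)
    stop("next_scheduled_time must exceed last_observed_time for dropouts")
  structure(list(subject_id = subject_id,
                 last_observed_time = last_observed_time,
                 next_scheduled_time = next_scheduled_time, event = event),
            class = "copd_dropout_record")
}

#' Interval dropout probability
#'
#' Likelihood contribution of the dropout process: a subject observed last
#' at \eqn{t_{last}} who misses the visit at \eqn{t_{next}} contributes
#' \eqn{S(t_{last}) - S(t_{next})} (the event happened somewhere in the
#' interval); a completer contributes \eqn{S(t_{end})}.
#'
#' @param rec a [dropout_record()].
#' @param spec a [hazard_spec()].
#' @param ipred_path predicted-FEV1 path (weeks clock).
#' @return probability.
#' @export
interval_dropout_probability <- function(rec, spec, ipred_path) {
  stopifnot(inherits(rec, "copd_dropout_record"))
  if (rec$event == "completed")
    return(survivor(rec$next_scheduled_time, spec, ipred_path))
  s <- survivor(c(rec$last_observed_time, rec$next_scheduled_time), spec,
                ipred_path)
  if (s[2] > s[1] + 1e-12)
    stop("survivor function is non-monotone; integration bug")
  s[1] - s[2]
}

#' Sample dropout times
#'
#' Inverse-CDF sampling on a piecewise-constant hazard grid: with
#' \eqn{U \sim Unif(0,1)}, the event time solves
#' \eqn{\int_0^T h = -\log U}, located segment by segment.  For
#' time-varying baseline forms the hazard is frozen at the left endpoint of
#' each grid segment (grid refined to `grid_dt`).
#'
#' @param spec a [hazard_spec()].
#' @param ipred_path predicted-FEV1 path (weeks clock).
#' @param horizon trial duration (weeks), > 0.
#' @param n number of draws.
#' @param u optional uniform draws (for reproducibility / inversion tests);
#'   defaults to `runif(n)`.
#' @param grid_dt grid refinement (weeks) for non-constant baseline forms.
#' @return numeric vector of length `n`; `NA` where the sampled time exceeds
#'   the horizon (completer).
#' @export
sample_dropout_time <- function(spec, ipred_path, horizon, n = 1L,
                                u = NULL, grid_dt = 0.1) {
  stopifnot(horizon > 0)
  if (is.null(u)) u <- stats::runif(n) else n <- length(u)
  grid <- if (inherits(ipred_path, "copd_step_path"))
    attr(ipred_path, "times") else 0
  if (spec$form != "constant")
    grid <- union(grid, seq(0, horizon, by = grid_dt))
  grid <- sort(unique(c(grid[grid < horizon], horizon)))
  lo <- grid[-length(grid)]
  h <- hazard(lo, spec, ipred = ipred_path(lo))
  ch <- c(0, cumsum(h * diff(grid)))          # cumulative hazard at grid
  target <- -log(u)
  out <- rep(NA_real_, n)
  idx <- findInterval(target, ch, left.open = TRUE)
  hit <- target <= ch[length(ch)] & idx <= length(lo) & idx >= 1L
  out[hit] <- lo[idx[hit]] + (target[hit] - ch[idx[hit]]) / h[idx[hit]]
  out
}
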