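#' Dropout-aware visual predictive check
#'
#' Re-simulates the trial `n_sim` times under the candidate parameters —
#' trajectories, residual error *and* dropout, so that simulated records
#' are censored exactly like the data — conditioning on the observed
#' subjects' covariates and arm assignment.  Observed and simulated 5th,
#' 50th and 95th percentiles of the measurements are computed on the visit
#' bins (one bin per scheduled visit; the data lie on a grid, no
#' smoothing), optionally within strata, and the across-replicate 2.5-97.5%
#' envelope of each percentile is reported.
#'
#' @param ds a `copd_dataset`.
#' @param pop parameters to simulate under (e.g. a fit's `$pop`).
#' @param design the [trial_design()]; defaults to the dataset's attribute.
#' @param n_sim number of replicate trials, `>= 100`.
#' @param strata optional stratification columns, subset of
#'   `c("arm", "severity", "reversibility", "pics")`.
#' @param seed integer seed.
#' @return an object of class `copd_vpc`: a data.frame with columns
#'   `stratum`, `time`, `stat` (`p5`/`p50`/`p95`), `observed`, `sim_lo`,
#'   `sim_med`, `sim_hi`, plus attributes `n_sim` and `seed`.
#' @export
vpc <- function(ds, pop, design = attr(ds, "design"), n_sim = 200,
                strata = NULL, seed = 1) {
  stopifnot(n_sim >= 100)
  if (is.null(design)) stop("a trial design is required")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dat <- dataset_to_eng(ds)
  arm_col <- ds$ARM[!duplicated(ds$ID)]
  arm <- match(arm_col, names(design$arms))
  strat <- if (is.null(strata)) factor(rep("all", dat$n)) else {
    cols <- lapply(strata, function(s) {
      if (s == "arm") arm_col else dat$cov_df[[s]]
    })
    interaction(as.data.frame(cols), sep = ":", drop = FALSE)
  }
  if (any(table(strat) == 0))
    warning("stratum with no observations: ",
            paste(names(which(table(strat) == 0)), collapse = ", "))
  qs <- c(p5 = 0.05, p50 = 0.5, p95 = 0.95)
  pct <- function(y, obs) {
    # percentiles per stratum x bin on observed records
    out <- array(NA_real_, c(nlevels(strat), dat$J, 3),
                 dimnames = list(levels(strat), NULL, names(qs)))
    for (s in seq_len(nlevels(strat))) {
      rows <- which(strat == levels(strat)[s])
      for (j in seq_len(dat$J)) {
        v <- y[rows, j][obs[rows, j]]
        if (length(v)) out[s, j, ] <- stats::quantile(v, qs, names = FALSE)
      }
    }
    out
  }
  obs_p <- pct(dat$y, dat$obs)
  sims <- array(NA_real_, c(n_sim, nlevels(strat), dat$J, 3))
  for (r in seq_len(n_sim)) {
    s <- simulate_core(pop, design, dat$cov_df, arm)
    sims[r, , , ] <- pct(s$Y, s$obs)
  }
  env_lo <- apply(sims, c(2, 3, 4), stats::quantile, 0.025, na.rm = TRUE)
  env_med <- apply(sims, c(2, 3, 4), stats::quantile, 0.5, na.rm = TRUE)
  env_hi <- apply(sims, c(2, 3, 4), stats::quantile, 0.975, na.rm = TRUE)
  grid <- expand.grid(stratum = levels(strat), time = dat$times,
                      stat = names(qs), KEEP.OUT.ATTRS = FALSE)
  grid$observed <- as.vector(obs_p)
  grid$sim_lo <- as.vector(env_lo)
  grid$sim_med <- as.vector(env_med)
  grid$sim_hi <- as.vector(env_hi)
  structure(grid, class = c("copd_vpc", "data.frame"),
            n_sim = n_sim, seed = seed)
}

#' @export
plot.copd_vpc <- function(x, ...) {
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 7)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      group = .data$stat),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med, group = .data$stat),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed, group = .data$stat),
                       colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "time (weeks)", y = "trough FEV1 (L)",
                  title = "Visual predictive check (dropout-aware)")
}

#' Kaplan-Meier estimate of the dropout process
#'
#' Product-limit estimate of the probability of remaining in the trial.
#' Accepts either raw event times with an event indicator, or the
#' [dropout_records()] of a dataset (dropouts dated at their first missed
#' visit, completers right-censored at the trial end).
#'
#' @param time event/censoring times (weeks), or a `dropout_records()`
#'   data.frame.
#' @param event 1 = dropout, 0 = censored; ignored when `time` is a
#'   records data.frame.
#' @return a data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`, of class `copd_km`.
#' @export
kaplan_meier <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    stopifnot(all(c("next_scheduled_time", "event") %in% names(time)))
    event <- as.integer(time$event == "dropped")
    time <- time$next_scheduled_time
  }
  stopifnot(length(time) >= 1, length(event) == length(time))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "none")
  structure(data.frame(time = c(0, sf$time),
                       n_risk = c(length(time), sf$n.risk),
                       n_event = c(0, sf$n.event),
                       survival = c(1, sf$surv)),
            class = c("copd_km", "data.frame"))
}

#' Normalised prediction distribution errors
#'
#' Simulation-based residuals: the observed vector of every subject is
#' decorrelated with the mean and covariance of `K` replicate simulations
#' (Cholesky factorisation), ranked within the equally decorrelated
#' simulated vectors, and the rank — with a 1/(2K) continuity correction to
#' avoid infinite quantiles — is mapped through the standard-normal
#' quantile.  Under the true model the npde are standard normal.
#' Replicates are simulated at the observed design points conditional on
#' the observed covariates and arms; dropout is not re-simulated (the
#' comparison is at the observed records).
#'
#' @param ds a `copd_dataset`.
#' @param pop parameters to simulate under.
#' @param design the [trial_design()]; defaults to the dataset attribute.
#' @param K number of replicates, `>= 500`.
#' @param seed integer seed.
#' @return an object of class `copd_npde`: list with `npde` (data.frame
#'   `subject_id`, `time`, `dv`, `npde`) and `summary` (mean, variance,
#'   Kolmogorov-Smirnov statistic and p-value against N(0,1)).
#' @export
npde <- function(ds, pop, design = attr(ds, "design"), K = 1000, seed = 1) {
  stopifnot(K >= 500)
  if (is.null(design)) stop("a trial design is required")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dat <- dataset_to_eng(ds)
  arm <- match(ds$ARM[!duplicated(ds$ID)], names(design$arms))
  sims <- array(NA_real_, c(K, dat$n, dat$J))
  for (r in seq_len(K)) {
    s <- simulate_core(pop, design, dat$cov_df, arm, with_dropout = FALSE)
    sims[r, , ] <- s$Y
  }
  out <- vector("list", dat$n)
  warned <- FALSE
  for (i in seq_len(dat$n)) {
    oj <- which(dat$obs[i, ])
    y <- dat$y[i, oj]
    S <- sims[, i, oj, drop = TRUE]
    if (length(oj) == 1L) S <- matrix(S, ncol = 1)
    m <- colMeans(S)
    V <- stats::cov(S)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      if (!warned) {
        warning("singular simulated covariance; ridge regularisation used")
        warned <- TRUE
      }
      L <- chol(V + diag(1e-8 * mean(diag(V)), length(oj)))
    }
    yd <- backsolve(L, y - m, transpose = TRUE)
    Sd <- t(backsolve(L, t(sweep(S, 2, m)), transpose = TRUE))
    pde <- (colSums(Sd < rep(yd, each = K)) ) / K
    pde <- pmin(pmax(pde, 1 / (2 * K)), 1 - 1 / (2 * K))
    out[[i]] <- data.frame(subject_id = dat$ids[i], time = dat$times[oj],
                           dv = y, npde = stats::qnorm(pde))
  }
  res <- do.call(rbind, out)
  ks <- suppressWarnings(stats::ks.test(res$npde, "pnorm"))
  structure(list(npde = res,
                 summary = c(mean = mean(res$npde),
                             variance = stats::var(res$npde),
                             ks_statistic = unname(ks$statistic),
                             ks_p = ks$p.value)),
            class = "copd_npde")
}

#' @export
print.copd_npde <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "NPDE over %d observations: mean %.4f, variance %.4f, KS D %.4f (p %.3g)\n",
    nrow(x$npde), s["mean"], s["variance"], s["ks_statistic"], s["ks_p"]))
  invisible(x)
}

# predictions on the dataset grid for given etas (rows match dat subjects)
predict_grid <- function(pop, dat, eta = NULL) {
  th <- pop_to_th(pop, dat)
  if (is.null(eta)) eta <- matrix(0, dat$n, 0)
  A <- exposure_matrix(rep(pop$kde, dat$n), dat$times, dat$regimen,
                       dat$active)
  one <- rep(1, dat$n)
  m <- function(p) if (is.null(th$mult[[p]])) one else th$mult[[p]]
  ec <- function(p) if (p %in% colnames(eta)) exp(eta[, p]) else one
  emax_t <- th$tv_emax * m("emax")
  eng_traj(th$tv_int_dis * m("int_dis") * ec("int_dis"),
           emax_t * ec("emax"),
           th$ratio_edk50_emax * emax_t * ec("edk50"),
           th$kin * m("kin") * ec("kin"),
           th$slope, A, dat$times, th$mode)
}

#' Goodness-of-fit table
#'
#' Per-observation predictions and residuals of a converged fit: `PRED`
#' (typical prediction, random effects at zero), `IPRED` (empirical-Bayes
#' individual prediction), `RES = DV - PRED`, and the individual weighted
#' residual `IWRES = (DV - IPRED) / sd`, where `sd` is the residual error
#' at `IPRED`.
#'
#' @param ds a `copd_dataset`.
#' @param fit a [fit_joint()] result.
#' @return a data.frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`,
#'   `RES`, `IWRES`.
#' @export
gof_tables <- function(ds, fit) {
  stopifnot(inherits(fit, "copd_fit"))
  dat <- dataset_to_eng(ds)
  eta <- as.matrix(fit$eta[match(dat$ids, fit$eta$subject_id), -1,
                           drop = FALSE])
  colnames(eta) <- fit$settings$iiv_on
  pred <- predict_grid(fit$pop, dat)
  ipred <- predict_grid(fit$pop, dat, eta)
  idx <- which(dat$obs, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sd <- sqrt(fit$pop$sigma_add^2 + (fit$pop$sigma_prop * ipred[idx])^2)
  data.frame(ID = dat$ids[idx[, 1]], TIME = dat$times[idx[, 2]],
             DV = dat$y[idx], PRED = pred[idx], IPRED = ipred[idx],
             RES = dat$y[idx] - pred[idx],
             IWRES = (dat$y[idx] - ipred[idx]) / sd)
}
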