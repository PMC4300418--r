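#' Stepwise covariate modelling
#'
#' Forward inclusion / backward elimination of covariate-parameter
#' relations by likelihood-ratio criteria on the MOFV.  Forward: at each
#' round every remaining candidate is added to the current model and
#' refitted; the candidate with the largest MOFV drop is included while
#' that drop is at least `forward` (3.84, chi-square p < 0.05 at 1 df; a
#' drop exactly at the threshold is included).  Ties are broken by the
#' larger drop, then lexicographic (covariate, parameter) order.
#' Backward: included covariates whose removal raises the MOFV by at most
#' `backward` (11 points, p <= 0.001) are deleted one at a time, least
#' informative first.  Candidates whose refit fails are logged and
#' skipped.
#'
#' Continuous candidates enter as power effects centred at their dataset
#' median; categorical candidates as multiplicative effects.
#'
#' @param ds a `copd_dataset`.
#' @param pop base-model starting parameters (its covariate effects, if
#'   any, stay fixed).
#' @param candidates data.frame with columns `covariate` and `parameter`.
#' @param estimate base parameters to estimate alongside each candidate
#'   theta (see [fit_joint()]).
#' @param forward,backward inclusion / retention thresholds on the MOFV.
#' @param ... passed to [fit_joint()] (`iiv_on`, `include_dropout`,
#'   `control`, ...).
#' @return list with `pop` (final parameters), `included` (data.frame of
#'   retained relations), `steps` (per-step MOFV table) and `final_fit`.
#' @export
covariate_step <- function(ds, pop, candidates,
                           estimate = c("tv_int_dis", "sigma_add",
                                        "omega_int_dis"),
                           forward = 3.84, backward = 11, ...) {
  stopifnot(all(c("covariate", "parameter") %in% names(candidates)))
  dots <- list(...)
  dots$control <- utils::modifyList(list(refine = FALSE, iter.max = 80L),
                                    dots$control %||% list())
  dat <- dataset_to_eng(ds)
  make_effect <- function(covariate, parameter) {
    v <- dat$cov_df[[covariate]]
    if (is.null(v)) stop("candidate covariate '", covariate,
                         "' not in dataset")
    if (is.numeric(v))
      covariate_effect(covariate, parameter, "power", 0,
                       reference = stats::median(v))
    else covariate_effect(covariate, parameter, "multiplicative", 1)
  }
  cand <- candidates[order(candidates$covariate, candidates$parameter), ,
                     drop = FALSE]
  cand$key <- paste0("theta_", cand$covariate, "_", cand$parameter)
  included <- character(0)
  steps <- list()
  fit_with <- function(keys) {
    p2 <- pop
    p2$covariate_effects <- c(pop$covariate_effects,
                              lapply(which(cand$key %in% keys), function(k)
                                make_effect(cand$covariate[k],
                                            cand$parameter[k])))
    do.call(fit_joint, c(list(dat, p2, estimate = c(estimate, keys),
                              compute_se = FALSE), dots))
  }
  base_fit <- fit_with(character(0))
  current <- base_fit
  # forward inclusion
  repeat {
    remaining <- setdiff(cand$key, included)
    if (!length(remaining)) break
    best <- NULL
    for (key in remaining) {
      f <- tryCatch(fit_with(c(included, key)), error = function(e) {
        warning("candidate ", key, " failed to fit: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(f)) next
      delta <- current$mofv - f$mofv
      steps[[length(steps) + 1L]] <- data.frame(
        phase = "forward", candidate = key, mofv = f$mofv,
        delta_mofv = delta)
      if (is.null(best) || delta > best$delta) # ties -> first in lex order
        best <- list(key = key, delta = delta, fit = f)
    }
    if (is.null(best) || best$delta < forward) break
    included <- c(included, best$key)
    current <- best$fit
  }
  # backward deletion
  repeat {
    if (!length(included)) break
    worst <- NULL
    for (key in included) {
      f <- tryCatch(fit_with(setdiff(included, key)),
                    error = function(e) NULL)
      if (is.null(f)) next
      rise <- f$mofv - current$mofv
      steps[[length(steps) + 1L]] <- data.frame(
        phase = "backward", candidate = key, mofv = f$mofv,
        delta_mofv = rise)
      if (is.null(worst) || rise < worst$rise)
        worst <- list(key = key, rise = rise, fit = f)
    }
    if (is.null(worst) || worst$rise > backward) break
    included <- setdiff(included, worst$key)
    current <- worst$fit
  }
  list(pop = current$pop,
       included = cand[cand$key %in% included,
                       c("covariate", "parameter", "key")],
       steps = do.call(rbind, steps),
       base_mofv = base_fit$mofv,
       final_fit = current)
}

#' Case-resampling bootstrap of the joint fit
#'
#' Resamples subjects with replacement, refits each replicate, and reports
#' percentile 90% confidence intervals (5th to 95th percentile) for every
#' estimated parameter.  Non-converged or failed replicates are counted and
#' excluded; more than 50% failures aborts with diagnostics.
#'
#' @param ds a `copd_dataset`.
#' @param pop starting parameters.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @param ... passed to [fit_joint()] (`estimate`, `iiv_on`, ...).
#' @return list with `ci` (data.frame: parameter, lower, upper, median),
#'   `estimates` (replicate-by-parameter matrix) and `n_failed`.
#' @export
bootstrap_fit <- function(ds, pop = default_pop(), n_boot = 100, seed = 1,
                          ...) {
  stopifnot(n_boot >= 2)
  ids <- unique(ds$ID)
  rows_by_id <- split(seq_len(nrow(ds)), ds$ID)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dots <- list(...)
  dots$control <- utils::modifyList(list(refine = FALSE, iter.max = 80L),
                                    dots$control %||% list())
  est <- NULL; n_failed <- 0L; msgs <- character(0)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      d <- ds[rows_by_id[[as.character(take[k])]], , drop = FALSE]
      d$ID <- k
      d
    })
    db <- do.call(rbind, pieces)
    class(db) <- class(ds)
    attr(db, "design") <- attr(ds, "design")
    f <- tryCatch(do.call(fit_joint, c(list(db, pop, compute_se = FALSE),
                                       dots)),
                  error = function(e) e)
    if (inherits(f, "error") || f$convergence != "converged") {
      n_failed <- n_failed + 1L
      if (inherits(f, "error")) msgs <- c(msgs, conditionMessage(f))
      next
    }
    est <- rbind(est, coef(f))
  }
  if (n_failed > n_boot / 2)
    stop("more than half of the bootstrap replicates failed (", n_failed,
         "/", n_boot, "): ", paste(utils::head(unique(msgs), 3),
                                   collapse = "; "))
  ci <- data.frame(
    parameter = colnames(est),
    lower = apply(est, 2, stats::quantile, 0.05),
    median = apply(est, 2, stats::quantile, 0.5),
    upper = apply(est, 2, stats::quantile, 0.95), row.names = NULL)
  list(ci = ci, estimates = est, n_failed = n_failed)
}
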