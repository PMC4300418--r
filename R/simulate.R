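#' Trial design
#'
#' Arms, dosing, visit schedule and size of a simulated COPD trial.  Trough
#' FEV1 is sampled on a regular visit grid (the pooled trials measured at
#' intervals between two and four weeks); the default design is two balanced
#' arms (placebo and 50 ug twice daily), 24 weeks with visits every 4 weeks.
#'
#' @param arms named list of [dose_regimen()] objects, one per arm.
#' @param allocation numeric vector of allocation fractions, summing to 1.
#' @param duration trial duration (weeks).
#' @param visit_interval weeks between visits, in `[2, 4]`.
#' @param n_subjects cohort size.
#' @param seed default simulation seed for this design.
#' @return an object of class `copd_design`.
#' @export
trial_design <- function(arms = list(placebo = dose_regimen(0),
                                     salmeterol = dose_regimen(50)),
                         allocation = c(0.5, 0.5),
                         duration = 24, visit_interval = 4,
                         n_subjects = 2000, seed = 20140918) {
  stopifnot(length(arms) == length(allocation),
            abs(sum(allocation) - 1) < 1e-8,
            visit_interval >= 2, visit_interval <= 4,
            duration >= visit_interval, n_subjects >= 1)
  if (is.null(names(arms))) names(arms) <- paste0("arm", seq_along(arms))
  structure(list(arms = arms, allocation = allocation, duration = duration,
                 visit_interval = visit_interval, n_subjects = n_subjects,
                 seed = seed),
            class = "copd_design")
}

visit_times_days <- function(design)
  seq(0, design$duration, by = design$visit_interval) * 7

# forward-simulate the visit grid for given covariates and arm assignment
# (uses the current RNG state; callers manage seeding).  Returns matrices
# over subjects x visits: F (noise-free), Y (with residual error), obs
# (post-dropout observation mask) and drop_m (last observed visit index for
# dropouts, NA for completers).
simulate_core <- function(pop, design, cov_df, arm, with_dropout = TRUE,
                          with_noise = TRUE) {
  n <- nrow(cov_df)
  omega <- pop$omega
  keep <- diag(omega) > 0
  eta <- matrix(0, n, sum(keep),
                dimnames = list(NULL, rownames(omega)[keep]))
  if (any(keep))
    eta[] <- MASS::mvrnorm(n, mu = rep(0, sum(keep)),
                           Sigma = omega[keep, keep, drop = FALSE])

  typ <- apply_covariates(pop, cov_df)
  ind <- list(
    int_dis = typ$int_dis, emax = typ$emax, edk50 = typ$edk50,
    kin = typ$kin, slope = typ$slope_dis, kde = typ$kde)
  for (p in colnames(eta)) {
    tgt <- if (p == "slope_dis") "slope" else p
    ind[[tgt]] <- ind[[tgt]] * exp(eta[, p])
  }

  times <- visit_times_days(design)
  J <- length(times)
  if (any(ind$int_dis + ind$slope * times[J] <= 0))
    stop("disease status became non-positive for at least one subject; ",
         "check slope and horizon")

  # exposure at troughs per arm (kde may carry IIV)
  A <- matrix(0, n, J)
  for (k in seq_along(design$arms)) {
    act <- arm == k
    if (any(act))
      A[act, ] <- exposure_matrix(ind$kde, times, design$arms[[k]],
                                  act)[act, , drop = FALSE]
  }
  F <- eng_traj(ind$int_dis, ind$emax, ind$edk50, ind$kin, ind$slope, A,
                times, pop$drug_effect_mode)

  # dropout via inverse CDF on the piecewise-constant hazard grid
  hz <- pop$hazard
  wk <- times / 7
  drop_m <- rep(NA_integer_, n)   # last observed visit index if dropped
  if (with_dropout && hz$beta0 > 0) {
    lin <- hz$beta2 * F[, -J, drop = FALSE]
    if (hz$beta1 != 0)
      stop("simulation of an observed-FEV1 hazard term (beta1 != 0) is not ",
           "supported; the final model uses beta2 on predicted FEV1")
    base <- switch(hz$form,
      constant = rep(hz$beta0, J - 1L),
      exponential = hz$beta0 * exp(hz$shape * wk[-J]),
      weibull = hz$beta0 * hz$shape * pmax(wk[-J], 1e-12)^(hz$shape - 1))
    h <- sweep(exp(lin), 2, base, "*")
    hdw <- sweep(h, 2, diff(wk), "*")
    cumH <- t(apply(hdw, 1, cumsum))
    target <- -log(stats::runif(n))
    for (i in seq_len(n)) {
      j <- which(target[i] <= cumH[i, ])[1]
      if (!is.na(j)) drop_m[i] <- j
    }
  }

  obs <- matrix(TRUE, n, J)
  for (i in which(!is.na(drop_m))) obs[i, (drop_m[i] + 1L):J] <- FALSE

  Y <- F
  if (with_noise && (pop$sigma_add > 0 || pop$sigma_prop > 0)) {
    eps <- matrix(stats::rnorm(n * J), n, J)
    err_model <- if (pop$sigma_prop > 0 && pop$sigma_add > 0) "combined"
      else if (pop$sigma_prop > 0) "proportional" else "additive"
    Y <- matrix(residual_error(as.vector(F), pop$sigma_add, pop$sigma_prop,
                               as.vector(eps), model = err_model), n, J)
  }
  list(times = times, F = F, Y = Y, obs = obs, drop_m = drop_m, eta = eta,
       arm = arm)
}

#' Simulate a virtual COPD trial
#'
#' Full forward simulation of the joint model: draw baseline covariates,
#' draw lognormal random effects from the population IIV matrix, build
#' individual parameters, solve the FEV1 trajectory on the visit grid,
#' sample a dropout time from the predicted-FEV1-linked hazard, censor
#' observations after dropout, and add residual error.
#'
#' @param pop a [pop_parameters()] object.
#' @param design a [trial_design()].
#' @param dist a [covariate_distributions()] object.
#' @param seed integer seed; defaults to `design$seed`.
#' @param covariates optional pre-sampled covariate data.frame (with an
#'   optional `arm` column) used instead of fresh draws — used by the
#'   diagnostics to re-simulate conditional on an observed design.
#' @return a `copd_dataset`: a data.frame in a NONMEM-style rectangular
#'   dialect with columns `ID`, `TIME` (days), `DV` (L), `AMT` (ug), `II`
#'   (h), `ADDL`, `EVID` (0 observation, 1 dose, 3 dropout/end record),
#'   `MDV`, `DROPOUT`, `ARM` and the covariate columns.  Attributes carry
#'   the design and generating seed.
#' @export
simulate_trial <- function(pop, design = trial_design(),
                           dist = covariate_distributions(),
                           seed = design$seed, covariates = NULL) {
  stopifnot(inherits(pop, "copd_pop"), inherits(design, "copd_design"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- if (is.null(covariates)) design$n_subjects else nrow(covariates)

  counts <- diff(c(0L, round(cumsum(design$allocation) * n)))
  if (is.null(covariates)) {
    cov_df <- sample_covariates(n, dist)
    arm <- sample(rep(seq_along(design$arms), times = counts))
  } else {
    cov_df <- covariates
    arm <- if (!is.null(covariates$arm))
      match(covariates$arm, names(design$arms))
    else sample(rep(seq_along(design$arms), times = counts))
    cov_df$arm <- NULL
  }

  sim <- simulate_core(pop, design, cov_df, arm)
  times <- sim$times; J <- length(times)
  F <- sim$F; Y <- sim$Y; obs <- sim$obs; drop_m <- sim$drop_m

  rows <- vector("list", n)
  arm_names <- names(design$arms)
  for (i in seq_len(n)) {
    oj <- which(obs[i, ])
    reg <- design$arms[[arm[i]]]
    obs_rows <- data.frame(ID = i, TIME = times[oj], DV = Y[i, oj],
                           AMT = NA_real_, II = NA_real_, ADDL = NA_real_,
                           EVID = 0L, MDV = 0L, DROPOUT = 0L)
    dose_rows <- NULL
    if (reg$dose_amount > 0) {
      n_doses <- floor((reg$end_time - reg$start_time) /
                         (reg$interval / 24)) + 1L
      dose_rows <- data.frame(ID = i, TIME = reg$start_time,
                              DV = NA_real_, AMT = reg$dose_amount,
                              II = reg$interval, ADDL = n_doses - 1L,
                              EVID = 1L, MDV = 1L, DROPOUT = 0L)
    }
    dropped <- !is.na(drop_m[i])
    term_time <- if (dropped) times[drop_m[i] + 1L] else times[J]
    term_rows <- data.frame(ID = i, TIME = term_time, DV = NA_real_,
                            AMT = NA_real_, II = NA_real_, ADDL = NA_real_,
                            EVID = 3L, MDV = 1L,
                            DROPOUT = as.integer(dropped))
    rows[[i]] <- rbind(dose_rows, obs_rows, term_rows)
  }
  out <- do.call(rbind, rows)
  out$ARM <- arm_names[arm[out$ID]]
  for (cc in names(cov_df)) out[[cc]] <- cov_df[[cc]][out$ID]
  out <- out[order(out$ID, out$TIME, out$EVID), ]
  rownames(out) <- NULL
  structure(out, class = c("copd_dataset", "data.frame"),
            design = design, seed = seed)
}

#' Write / read a trial dataset
#'
#' CSV round trip of the NONMEM-style rectangular dataset produced by
#' [simulate_trial()]; missing `DV` values are encoded through the `MDV`
#' flag and written as `.`.  `read_dataset` validates the file and reports
#' malformed rows with their line numbers.
#'
#' @param ds a `copd_dataset`.
#' @param path file path.
#' @return `read_dataset` returns a `copd_dataset`; `write_dataset`
#'   invisibly returns `path`.
#' @export
write_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  num <- c("DV", "AMT", "II", "ADDL")
  for (cc in num) out[[cc]] <- ifelse(is.na(out[[cc]]), ".",
                                      format(out[[cc]], digits = 12,
                                             trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("ID", "TIME", "DV", "AMT", "II", "ADDL", "EVID", "MDV",
            "DROPOUT")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("dataset is missing columns: ", paste(miss, collapse = ", "))
  to_num <- function(x, col) {
    x[x == "."] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop("non-numeric ", col, " at file line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    v
  }
  ds <- raw
  for (cc in c("ID", "TIME", "DV", "AMT", "II", "ADDL", "EVID", "MDV",
               "DROPOUT"))
    ds[[cc]] <- to_num(raw[[cc]], cc)
  for (cc in setdiff(names(ds), need))
    if (!anyNA(suppressWarnings(as.numeric(ds[[cc]]))))
      ds[[cc]] <- as.numeric(ds[[cc]])
  # per-subject validation
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id & ds$EVID == 0, ]
    if (nrow(sub) == 0)
      stop("subject ", id, " has no observation records")
    if (is.unsorted(sub$TIME, strictly = TRUE))
      stop("non-monotone observation times for subject ", id)
  }
  ds$ID <- as.integer(ds$ID)
  for (cc in c("EVID", "MDV", "DROPOUT", "ADDL"))
    ds[[cc]] <- as.integer(ds[[cc]])
  structure(ds, class = c("copd_dataset", "data.frame"))
}

#' Dropout records of a dataset
#'
#' Extracts one row per subject describing the terminal status: dropouts
#' carry the last observed and next scheduled visit times; completers carry
#' the trial end time.
#'
#' @param ds a `copd_dataset`.
#' @return a data.frame with columns `subject_id`, `last_observed_time`,
#'   `next_scheduled_time` (weeks) and `event`.
#' @export
dropout_records <- function(ds) {
  ids <- unique(ds$ID)
  out <- lapply(ids, function(id) {
    obs <- ds[ds$ID == id & ds$EVID == 0, ]
    term <- ds[ds$ID == id & ds$EVID == 3, ]
    dropped <- nrow(term) > 0 && term$DROPOUT[1] == 1
    data.frame(subject_id = id,
               last_observed_time = max(obs$TIME) / 7,
               next_scheduled_time = if (nrow(term)) term$TIME[1] / 7
                 else max(obs$TIME) / 7,
               event = if (dropped) "dropped" else "completed")
  })
  do.call(rbind, out)
}

# convert a dataset to the rectangular engine representation; the visit
# grid is the union of observation times (all subjects share the design
# grid, dropouts simply stop early)
dataset_to_eng <- function(ds, design = attr(ds, "design")) {
  times <- sort(unique(ds$TIME[ds$EVID == 0]))
  ids <- unique(ds$ID)
  n <- length(ids); J <- length(times)
  y <- matrix(NA_real_, n, J); obs <- matrix(FALSE, n, J)
  drop_m <- rep(NA_integer_, n)
  idmap <- match(ds$ID, ids)
  o <- ds$EVID == 0
  jj <- match(ds$TIME[o], times)
  y[cbind(idmap[o], jj)] <- ds$DV[o]
  obs[cbind(idmap[o], jj)] <- !is.na(ds$DV[o]) & ds$MDV[o] == 0
  tm <- ds$EVID == 3 & ds$DROPOUT == 1
  if (any(tm)) {
    nxt <- match(ds$TIME[tm], times)
    if (anyNA(nxt))
      stop("dropout record time off the visit grid for subject(s) ",
           paste(ds$ID[tm][is.na(nxt)], collapse = ", "))
    drop_m[idmap[tm]] <- nxt - 1L
  }
  first <- !duplicated(ds$ID)
  cov_cols <- setdiff(names(ds), c("ID", "TIME", "DV", "AMT", "II", "ADDL",
                                   "EVID", "MDV", "DROPOUT", "ARM"))
  cov_df <- as.data.frame(ds)[first, cov_cols, drop = FALSE]
  rownames(cov_df) <- NULL
  # regimen: from the dose records (one arm may be placebo)
  dose <- ds[ds$EVID == 1, ]
  if (nrow(dose)) {
    regimen <- dose_regimen(dose$AMT[1], dose$II[1], dose$TIME[1],
                            dose$TIME[1] + dose$ADDL[1] * dose$II[1] / 24)
    active <- ids %in% unique(dose$ID)
  } else {
    regimen <- dose_regimen(0)
    active <- rep(FALSE, n)
  }
  eng_data(times, y, obs, drop_m, active, cov_df, regimen, ids = ids)
}
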