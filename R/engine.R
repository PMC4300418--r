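# Internal vectorised engine: FEV1 trajectories, joint log-likelihood and
# batched Laplace marginalisation for all subjects of a trial at once.
# Subjects share one visit grid (times in days); the dropout clock is weeks.

# one closed-form turnover step, vectorised over subjects, safe at b == 0:
#   log(r)/b = (dt/d0) * log1p(x)/x  with  x = b*dt/d0
step_turnover_vec <- function(f0, d0, dt, b, kin_eff, kout_coef) {
  x <- pmax(b * dt / d0, -1 + 1e-12)   # rows with Dis <= 0 are invalidated
  lr <- ifelse(abs(x) < 1e-12, 1, log1p(x) / x) * dt / d0
  rp <- exp(-kout_coef * lr)
  r <- 1 + x
  f0 * rp + kin_eff * d0 * (r - rp) / (kout_coef + b)
}

# steady-state trough exposure at days `t` for per-subject kde (vectorised);
# zero for placebo rows
exposure_matrix <- function(kde, times, regimen, active) {
  n <- length(kde); J <- length(times)
  A <- matrix(0, n, J)
  if (!any(active) || regimen$dose_amount == 0) return(A)
  for (j in seq_len(J)) {
    if (times[j] <= regimen$start_time) next
    tau <- regimen$interval / 24
    rel <- times[j] - regimen$start_time
    m <- min(ceiling(rel / tau - 1e-9),
             floor((regimen$end_time - regimen$start_time) / tau) + 1)
    if (m < 1) next
    delta <- rel - (m - 1) * tau
    k <- kde[active]
    A[active, j] <- regimen$dose_amount * exp(-k * delta) *
      (1 - exp(-k * m * tau)) / (1 - exp(-k * tau))
  }
  A
}

# trajectory matrix F (n x J) given per-subject natural parameters
eng_traj <- function(int_dis, emax, edk50, kin, slope, A, times, mode) {
  n <- length(int_dis); J <- length(times)
  F <- matrix(0, n, J)
  F[, 1] <- int_dis + slope * times[1]
  for (j in seq_len(J - 1L)) {
    d0 <- int_dis + slope * times[j]
    dt <- times[j + 1L] - times[j]
    e <- emax * A[, j + 1L] / (edk50 + A[, j + 1L])
    if (mode == "multiplicative_kin") {
      F[, j + 1L] <- step_turnover_vec(F[, j], d0, dt, slope,
                                       kin * (1 + e), kin)
    } else if (mode == "additive_kin") {
      F[, j + 1L] <- step_turnover_vec(F[, j], d0, dt, slope, kin + e, kin)
    } else if (mode == "multiplicative_kout") {
      F[, j + 1L] <- step_turnover_vec(F[, j], d0, dt, slope, kin,
                                       kin * (1 + e))
    } else stop("mode not supported by the closed-form engine: ", mode)
  }
  F
}

# assemble engine data from per-subject design pieces
# y, obs: n x J; drop_m: last-observed grid index for dropouts, NA otherwise
eng_data <- function(times, y, obs, drop_m, arm_active, cov_df, regimen,
                     ids = seq_len(nrow(y))) {
  stopifnot(ncol(y) == length(times))
  list(times = times, wk = times / 7, n = nrow(y), J = length(times),
       y = y, obs = obs, drop_m = drop_m, active = arm_active,
       cov_df = cov_df, regimen = regimen, ids = ids)
}

# th: list(tv_int_dis, tv_emax, ratio_edk50_emax, kin, slope, kde,
#          sigma_add, sigma_prop, beta0, beta1, beta2, mode,
#          mult = list(int_dis=, emax=, kin=, slope_dis=),  # covariate mult
#          include_dropout = TRUE)
# eta: n x d matrix with colnames in {"int_dis","emax","kin","slope_dis",
#          "edk50","kde"}
# returns n-vector: log p(y_i, dropout_i | eta_i)
eng_loglik <- function(eta, dat, th, A = NULL) {
  n <- dat$n; J <- dat$J
  one <- rep(1, n)
  m <- function(p) if (is.null(th$mult[[p]])) one else th$mult[[p]]
  ecol <- function(p) if (!is.null(colnames(eta)) && p %in% colnames(eta))
    exp(eta[, p]) else one

  int_dis <- th$tv_int_dis * m("int_dis") * ecol("int_dis")
  emax_t <- th$tv_emax * m("emax")
  emax <- emax_t * ecol("emax")
  edk50 <- th$ratio_edk50_emax * emax_t * ecol("edk50")
  kin <- th$kin * m("kin") * ecol("kin")
  slope <- th$slope * m("slope_dis") * ecol("slope_dis")
  if (is.null(A)) {
    kde <- th$kde * ecol("kde")
    A <- exposure_matrix(kde, dat$times, dat$regimen, dat$active)
  }
  valid <- is.finite(int_dis) & int_dis > 0 &
    is.finite(emax) & is.finite(edk50) & edk50 > 0 & is.finite(kin) &
    int_dis + slope * dat$times[J] > 0
  valid[is.na(valid)] <- FALSE
  if (!any(valid)) return(rep(-Inf, n))
  int_dis[!valid] <- 1; emax[!valid] <- 0; edk50[!valid] <- 1
  F <- eng_traj(pmax(int_dis, 1e-6), emax, edk50, kin, slope, A,
                dat$times, th$mode)

  # observation likelihood (additive / combined residual)
  sd2 <- th$sigma_add^2 + (th$sigma_prop * F)^2
  res2 <- (dat$y - F)^2
  llm <- -0.5 * (res2 / sd2 + log(2 * pi * sd2))
  llm[!dat$obs] <- 0
  ll <- rowSums(llm)

  if (isTRUE(th$include_dropout)) {
    dw <- diff(dat$wk)
    lin <- th$beta2 * F[, -J, drop = FALSE]
    if (th$beta1 != 0)
      lin <- lin + th$beta1 * dat$y[, -J, drop = FALSE]
    h <- th$beta0 * exp(lin)                     # n x (J-1), per-week
    hdw <- sweep(h, 2, dw, "*")
    cumH <- matrix(0, n, J)                      # cum hazard at grid points
    for (j in seq_len(J - 1L)) cumH[, j + 1L] <- cumH[, j] + hdw[, j]
    comp <- is.na(dat$drop_m)
    lld <- numeric(n)
    lld[comp] <- -cumH[comp, J]
    if (any(!comp)) {
      i <- which(!comp); mi <- dat$drop_m[i]
      lld[i] <- -cumH[cbind(i, mi)] + log1p(-exp(-hdw[cbind(i, mi)]))
    }
    ll <- ll + lld
  }
  ll[!valid | !is.finite(ll)] <- -Inf
  ll
}

# batched Laplace marginal log-likelihood over diagonal random effects.
# omega2: named vector of eta variances (length d >= 1)
# Newton with finite-difference derivatives and per-subject step damping.
laplace_batch <- function(dat, th, omega2, eta0 = NULL, A = NULL,
                          h_fd = 1e-4, grad_tol = 1e-8, max_iter = 60L) {
  d <- length(omega2)
  nm <- names(omega2)
  n <- dat$n
  if (is.null(A)) {
    kde_eta <- "kde" %in% nm
    if (!kde_eta)
      A <- exposure_matrix(rep(th$kde, n), dat$times, dat$regimen,
                           dat$active)
  }
  if (is.null(eta0)) eta0 <- matrix(0, n, d)
  colnames(eta0) <- nm
  g <- function(eta) {
    pen <- 0.5 * colSums(t(eta^2) / omega2) +
      0.5 * sum(log(2 * pi * omega2))
    eng_loglik(eta, dat, th, A = A) - pen
  }
  eta <- eta0
  gc_cur <- g(eta)
  gc_cur[!is.finite(gc_cur)] <- -Inf
  lm_ridge <- rep(0, n)          # Levenberg-Marquardt ridge per subject
  active <- rep(TRUE, n)         # subjects still iterating
  for (it in seq_len(max_iter)) {
    grad <- matrix(0, n, d)
    hess <- array(0, c(n, d, d))
    for (k in seq_len(d)) {
      ek <- matrix(0, n, d); ek[, k] <- h_fd
      fpk <- g(eta + ek); fmk <- g(eta - ek)
      grad[, k] <- (fpk - fmk) / (2 * h_fd)
      hess[, k, k] <- (fpk - 2 * gc_cur + fmk) / h_fd^2
    }
    if (d > 1) {
      for (k in seq_len(d - 1L)) for (l in (k + 1L):d) {
        ek <- matrix(0, n, d); ek[, k] <- h_fd
        el <- matrix(0, n, d); el[, l] <- h_fd
        cpp <- g(eta + ek + el); cpm <- g(eta + ek - el)
        cmp <- g(eta - ek + el); cmm <- g(eta - ek - el)
        hess[, k, l] <- hess[, l, k] <- (cpp - cpm - cmp + cmm) / (4 * h_fd^2)
      }
    }
    # rows whose likelihood is -Inf at the current iterate produce
    # non-finite differences; make them inert (zero step, inactive)
    grad[!is.finite(grad)] <- 0
    hess[!is.finite(hess)] <- 0
    solve_step <- function(r) {
      # solve (-H + r I) step = grad, vectorised for d <= 2
      step <- matrix(0, n, d)
      if (d == 1L) {
        step[, 1] <- grad[, 1] / pmax(-hess[, 1, 1] + r, 1e-8)
      } else if (d == 2L) {
        a11 <- -hess[, 1, 1] + r; a22 <- -hess[, 2, 2] + r
        a12 <- -hess[, 1, 2]
        det <- pmax(a11 * a22 - a12^2, 1e-12)
        step[, 1] <- (a22 * grad[, 1] - a12 * grad[, 2]) / det
        step[, 2] <- (a11 * grad[, 2] - a12 * grad[, 1]) / det
      } else {
        for (i in seq_len(n)) {
          nh <- -hess[i, , ] + diag(r[i], d)
          ev <- min(eigen(nh, symmetric = TRUE, only.values = TRUE)$values)
          if (ev <= 1e-8) nh <- nh + diag(abs(ev) + 1e-4, d)
          step[i, ] <- solve(nh, grad[i, ])
        }
      }
      step
    }
    # ensure a positive-definite system before the first try
    mind <- if (d == 1L) -hess[, 1, 1] else if (d == 2L)
      pmin(-hess[, 1, 1], -hess[, 2, 2]) else
      apply(hess, 1, function(hh) min(-diag(matrix(hh, d, d))))
    lm_ridge <- pmax(lm_ridge, ifelse(mind <= 0, -mind + 1e-2, 0))
    pending <- active
    eta_new <- eta; g_new <- gc_cur
    for (tries in 1:12) {
      step <- solve_step(lm_ridge)
      step[!pending, ] <- 0
      eta_try <- eta + step
      g_try <- g(eta_try)
      g_try[!is.finite(g_try)] <- -Inf
      ok <- pending & (g_try >= gc_cur - 1e-10)
      eta_new[ok, ] <- eta_try[ok, ]
      g_new[ok] <- g_try[ok]
      pending <- pending & !ok
      if (!any(pending)) break
      lm_ridge[pending] <- pmax(lm_ridge[pending] * 10, 1e-2)
    }
    moved <- sqrt(rowSums((eta_new - eta)^2))
    progress <- g_new - gc_cur
    eta <- eta_new; gc_cur <- g_new
    lm_ridge <- lm_ridge / 10                  # relax the ridge gradually
    # converge on the eta gradient, not the step: a large ridge can make
    # steps tiny while the mode has not been reached
    gnorm <- apply(abs(grad), 1, max)
    stalled <- moved < 1e-14 & progress < 1e-14   # -Inf / degenerate rows
    active <- active & gnorm > grad_tol & !stalled
    if (!any(active)) break
  }
  # final curvature at the mode for the Laplace determinant
  grad <- matrix(0, n, d); hess <- array(0, c(n, d, d))
  for (k in seq_len(d)) {
    ek <- matrix(0, n, d); ek[, k] <- h_fd
    fpk <- g(eta + ek); fmk <- g(eta - ek)
    grad[, k] <- (fpk - fmk) / (2 * h_fd)
    hess[, k, k] <- (fpk - 2 * gc_cur + fmk) / h_fd^2
  }
  if (d > 1) {
    for (k in seq_len(d - 1L)) for (l in (k + 1L):d) {
      ek <- matrix(0, n, d); ek[, k] <- h_fd
      el <- matrix(0, n, d); el[, l] <- h_fd
      hess[, k, l] <- hess[, l, k] <-
        (g(eta + ek + el) - g(eta + ek - el) -
           g(eta - ek + el) + g(eta - ek - el)) / (4 * h_fd^2)
    }
  }
  logdet <- if (d == 1L) {
    log(pmax(-hess[, 1, 1], 1e-12))
  } else if (d == 2L) {
    log(pmax(hess[, 1, 1] * hess[, 2, 2] - hess[, 1, 2]^2, 1e-12))
  } else {
    vapply(seq_len(n), function(i)
      determinant(-hess[i, , ], logarithm = TRUE)$modulus, numeric(1))
  }
  logdet[!is.finite(logdet)] <- log(1e-12)
  marg <- gc_cur + 0.5 * d * log(2 * pi) - 0.5 * logdet
  list(marginal = marg, eta = eta, converged = max(abs(grad)) < 1e-4,
       logdet = logdet)
}
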