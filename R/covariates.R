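#' Covariate marginal distributions for virtual COPD cohorts
#'
#' Marginal specifications for the baseline characteristics of a simulated
#' COPD population.  Categorical covariates are Bernoulli with the given
#' non-reference proportion; continuous covariates are scaled Beta
#' distributions matched to a printed median and range (pooled Phase II
#' demographics report medians and ranges but no dispersion, so a
#' two-parameter Beta on the stated range, with total concentration
#' `conc = alpha + beta`, is calibrated so its median hits the target).
#' Covariates are sampled independently; pass a function as `joint_sampler`
#' to [sample_covariates()] to impose dependence.
#'
#' Defaults reproduce the pooled-trial demographics: 30% female, 67% severe,
#' 26% reversible, 40% previous inhaled corticosteroid use, 42% smokers;
#' height median 170 cm on 135-203 cm, age median 65 y on 40-90 y.  Weight
#' (median 75 kg on 40-130 kg) has no printed counterpart and is a
#' package-chosen realistic marginal; BMI is derived from weight and height.
#'
#' @param p_female,p_severe,p_reversible,p_pics,p_smoker category
#'   proportions in `[0, 1]`.
#' @param height,age,weight lists with elements `min`, `max`, `median` and
#'   optionally `conc` (default 8).
#' @return an object of class `copd_cov_dist`.
#' @export
covariate_distributions <- function(p_female = 0.30, p_severe = 0.67,
                                    p_reversible = 0.26, p_pics = 0.40,
                                    p_smoker = 0.42,
                                    height = list(min = 135, max = 203,
                                                  median = 170),
                                    age = list(min = 40, max = 90,
                                               median = 65),
                                    weight = list(min = 40, max = 130,
                                                  median = 75)) {
  props <- c(p_female = p_female, p_severe = p_severe,
             p_reversible = p_reversible, p_pics = p_pics,
             p_smoker = p_smoker)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  cont <- list(height = height, age = age, weight = weight)
  cont <- lapply(cont, function(s) {
    stopifnot(s$min < s$max, s$median > s$min, s$median < s$max)
    if (is.null(s$conc)) s$conc <- 8
    s
  })
  structure(c(as.list(props), cont), class = "copd_cov_dist")
}

# calibrate Beta(a, conc - a) so the median of the scaled variable equals
# the target median; solved once per spec
scaled_beta_shapes <- function(spec) {
  m <- (spec$median - spec$min) / (spec$max - spec$min)
  f <- function(a) stats::qbeta(0.5, a, spec$conc - a) - m
  a <- stats::uniroot(f, c(0.2, spec$conc - 0.2), extendInt = "upX")$root
  c(shape1 = a, shape2 = spec$conc - a)
}

r_scaled_beta <- function(n, spec) {
  sh <- scaled_beta_shapes(spec)
  spec$min + (spec$max - spec$min) * stats::rbeta(n, sh[1], sh[2])
}

#' Sample a virtual COPD cohort
#'
#' Draws `n` baseline covariate vectors from the configured marginals.
#' Reproducible under a fixed seed; with `n` large the empirical marginals
#' converge to the configured values.
#'
#' @param n cohort size, > 0.
#' @param dist a [covariate_distributions()] object.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param joint_sampler optional function `(n, dist)` returning a complete
#'   covariate data.frame, replacing independent sampling.
#' @return a data.frame with columns `age`, `sex` ("female"/"male"),
#'   `height` (cm), `weight` (kg), `bmi` (kg/m^2), `severity`
#'   ("moderate"/"severe"), `reversibility`, `pics`, `smoking` ("no"/"yes").
#' @export
sample_covariates <- function(n, dist = covariate_distributions(),
                              seed = NULL, joint_sampler = NULL) {
  stopifnot(n > 0, inherits(dist, "copd_cov_dist"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (!is.null(joint_sampler)) return(joint_sampler(n, dist))
  height <- r_scaled_beta(n, dist$height)
  weight <- r_scaled_beta(n, dist$weight)
  data.frame(
    age = r_scaled_beta(n, dist$age),
    sex = ifelse(stats::runif(n) < dist$p_female, "female", "male"),
    height = height,
    weight = weight,
    bmi = weight / (height / 100)^2,
    severity = ifelse(stats::runif(n) < dist$p_severe, "severe", "moderate"),
    reversibility = ifelse(stats::runif(n) < dist$p_reversible, "yes", "no"),
    pics = ifelse(stats::runif(n) < dist$p_pics, "yes", "no"),
    smoking = ifelse(stats::runif(n) < dist$p_smoker, "yes", "no")
  )
}
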