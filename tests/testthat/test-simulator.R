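test_that("covariate marginals converge to the configured proportions", {
  cov <- sample_covariates(1e4, seed = 77)
  expect_equal(mean(cov$sex == "female"), 0.30, tolerance = 0.01 / 0.30)
  expect_equal(mean(cov$severity == "severe"), 0.67, tolerance = 0.01 / 0.67)
  expect_equal(mean(cov$reversibility == "yes"), 0.26, tolerance = 0.05)
  expect_equal(mean(cov$pics == "yes"), 0.40, tolerance = 0.04)
  expect_equal(median(cov$height), 170, tolerance = 0.01)
  expect_equal(median(cov$age), 65, tolerance = 0.01)
  expect_true(all(cov$height > 135 & cov$height < 203))
  expect_true(all(cov$age > 40 & cov$age < 90))
  expect_equal(cov$bmi, cov$weight / (cov$height / 100)^2)
  # determinism under a fixed seed
  expect_identical(cov, sample_covariates(1e4, seed = 77))
  # custom joint sampler hook
  js <- function(n, dist) data.frame(height = rep(170, n))
  expect_equal(sample_covariates(3, joint_sampler = js)$height,
               rep(170, 3))
})

test_that("degenerate simulation reproduces the structural curve exactly", {
  des <- trial_design(n_subjects = 10, seed = 5,
                      arms = list(placebo = dose_regimen(0)),
                      allocation = 1)
  # zero slope: FEV1 sits exactly on the constant disease status
  ds <- simulate_trial(bare_pop(tv_slope_dis = 0), des)
  obs <- ds[ds$EVID == 0, ]
  expect_equal(obs$DV, rep(1.16, nrow(obs)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero hazard: no dropout records at all
  expect_true(all(ds$DROPOUT == 0))
  expect_equal(sum(ds$EVID == 0), 10 * 7)
  # declining disease: the turnover response tracks Dis with a lag
  # bounded by |slope| / Kout once transients die out
  ds2 <- simulate_trial(bare_pop(), des)
  obs2 <- ds2[ds2$EVID == 0, ]
  dis <- disease_status(obs2$TIME, 1.16, -1e-4)
  expect_true(all(obs2$DV >= dis - 1e-12))
  expect_lt(max(abs(obs2$DV - dis)), 1e-4 / 0.1 + 1e-9)
})

test_that("active arm beats placebo at trial end under a positive Emax", {
  pop <- default_pop()
  ds <- simulate_trial(pop, trial_design(n_subjects = 2000, seed = 42))
  last <- ds[ds$EVID == 0 & ds$TIME == 168, ]
  tt <- t.test(last$DV[last$ARM == "salmeterol"],
               last$DV[last$ARM == "placebo"], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("no observation ever falls after a subject's dropout record", {
  pop <- default_pop()
  for (sd in c(3, 9)) {
    ds <- simulate_trial(pop, trial_design(n_subjects = 300, seed = sd))
    term <- ds[ds$EVID == 3 & ds$DROPOUT == 1, ]
    for (k in seq_len(nrow(term))) {
      obs_t <- ds$TIME[ds$ID == term$ID[k] & ds$EVID == 0]
      expect_true(all(obs_t < term$TIME[k]))
    }
  }
})

test_that("simulated residuals and random effects match sigma and omega", {
  pop <- pop_parameters(covariate_effects = list(),
                        omega = c(int_dis = 0.0625),
                        hazard = hazard_spec(beta0 = 0))
  n <- 1e4   # ~7e4 observation records
  ds <- simulate_trial(pop, trial_design(
    n_subjects = n, seed = 8,
    arms = list(placebo = dose_regimen(0)), allocation = 1))
  dat <- eng_of(ds)
  # placebo with zero drug effect and known slope: de-trended responses are
  # int_dis_i + noise, so the within-subject variance estimates sigma^2 and
  # the across-subject spread of the row means estimates omega
  y <- dat$y
  slope_term <- outer(rep(-1e-4, nrow(y)), dat$times)
  detr <- y - slope_term
  # detrended values are int_dis_i + noise: within-subject SD estimates sigma
  wsd <- sqrt(mean(apply(detr, 1, var)))
  se <- 0.13 / sqrt(2 * n * 6)
  expect_lt(abs(wsd - 0.13), 4 * se)
  # across-subject SD of log row-means estimates omega
  lm_ <- log(rowMeans(detr))
  expect_equal(sd(lm_), sqrt(0.0625 + 0.13^2 / 7 / 1.16^2),
               tolerance = 0.02)
})

test_that("with beta2 = 0 dropout is independent of treatment arm", {
  pop <- pop_parameters(covariate_effects = list(),
                        omega = c(int_dis = 0.0625, emax = 0.49),
                        hazard = hazard_spec(beta0 = 0.006, beta2 = 0))
  set.seed(1234)
  rejections <- 0L
  for (r in 1:100) {
    ds <- simulate_trial(pop, trial_design(n_subjects = 300, seed = 10000 + r))
    rec <- dropout_records(ds)
    arm <- ds$ARM[!duplicated(ds$ID)]
    tab <- table(arm, rec$event == "dropped")
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) 1)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5)   # expect ~1 rejection in 100 at the 1% level
})

test_that("dataset round-trips losslessly through the CSV dialect", {
  pop <- default_pop()
  ds <- simulate_trial(pop, trial_design(n_subjects = 3, seed = 21))
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  for (cc in c("ID", "TIME", "EVID", "MDV", "DROPOUT", "ARM", "sex",
               "severity"))
    expect_equal(back[[cc]], ds[[cc]], ignore_attr = TRUE)
  expect_equal(back$DV, ds$DV, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$AMT, ds$AMT, tolerance = 1e-9, ignore_attr = TRUE)
  # dropout flags preserved
  expect_identical(sum(back$DROPOUT), sum(ds$DROPOUT))
  unlink(path)
})

test_that("malformed files are rejected with informative errors", {
  pop <- default_pop()
  ds <- simulate_trial(pop, trial_design(n_subjects = 2, seed = 22))
  path <- tempfile(fileext = ".csv")
  # non-monotone times within a subject
  bad <- ds
  obs_rows <- which(bad$EVID == 0 & bad$ID == 1)
  bad$TIME[obs_rows[2]] <- bad$TIME[obs_rows[4]]
  bad$TIME[obs_rows[4]] <- 28
  write_dataset(bad, path)
  expect_error(read_dataset(path), "subject 1")
  # missing required column
  ds2 <- as.data.frame(ds); ds2$EVID <- NULL
  utils::write.csv(ds2, path, row.names = FALSE)
  expect_error(read_dataset(path), "missing columns")
  # non-numeric DV pinpointed by line
  txt <- readLines(write_dataset(ds, path))
  txt[3] <- sub("^([0-9]+,[0-9.]+),[0-9.]+", "\\1,oops", txt[3])
  writeLines(txt, path)
  expect_error(read_dataset(path), "line")
  unlink(path)
})

test_that("simulation is reproducible and seed-sensitive", {
  pop <- default_pop()
  d <- trial_design(n_subjects = 40, seed = 11)
  expect_identical(simulate_trial(pop, d), simulate_trial(pop, d))
  ds2 <- simulate_trial(pop, d, seed = 12)
  expect_false(identical(ds2$DV, simulate_trial(pop, d)$DV))
})
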