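test_that("degenerate trajectories are fitted exactly via fallback", {
  d <- expand.grid(subject_id = sprintf("S%02d", 1:6), visit_time = 0:4,
                   stringsAsFactors = FALSE)
  d$y <- 2 + 0.5 * d$visit_time               # every subject on one line
  fit <- fit_lme_change(d, "y", max_time = 5)
  expect_equal(fit$fixed_slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$fixed_intercept, 2, tolerance = 1e-12)
  expect_true(all(abs(extract_subject_slopes(fit) - 0.5) < 1e-12))

  d$y <- 7                                     # constant outcome
  fit0 <- fit_lme_change(d, "y", max_time = 5)
  expect_equal(fit0$fixed_slope, 0, tolerance = 1e-12)
  expect_gte(fit0$wald_p, 0.99)

  expect_error(fit_lme_change(d[d$subject_id == "S01", ], "y"),
               ">= 2 subjects")
})

test_that("the fixed slope and subject slopes recover a known world", {
  set.seed(101)
  sim <- fixture_longitudinal(200, 0:3, slope_mean = 0.3, slope_sd = 0.1,
                              noise_sd = 0.2)
  fit <- fit_lme_change(sim$data, "y", max_time = 5)
  expect_identical(fit$fallback, "none")
  expect_lt(abs(fit$fixed_slope - 0.3), 3 * fit$slope_se)
  expect_equal(fit$wald_stat, (fit$fixed_slope / fit$slope_se)^2,
               tolerance = 1e-12)
  # slope SD : per-observation noise = 2 : 1
  sim2 <- fixture_longitudinal(200, 0:3, slope_mean = 0.3, slope_sd = 0.2,
                               noise_sd = 0.1)
  fit2 <- fit_lme_change(sim2$data, "y", max_time = 5)
  eb <- extract_subject_slopes(fit2)
  expect_gt(stats::cor(eb[names(sim2$slopes)], sim2$slopes), 0.9)
})

test_that("the observation window is honoured", {
  set.seed(102)
  sim <- fixture_longitudinal(40, 0:5, slope_mean = 0.2, slope_sd = 0.05)
  d <- sim$data
  # corrupt every visit beyond 3 years; a theta fit must not see them
  d$y[d$visit_time > 3] <- d$y[d$visit_time > 3] + 100
  d$theta <- d$y
  fit <- fit_lme_change(d, "theta")
  expect_identical(fit$n_obs, sum(d$visit_time <= 3))
  expect_lt(abs(fit$fixed_slope - 0.2), 0.1)
})

test_that("slope regression recovers exact and simulated couplings", {
  set.seed(103)
  n <- 120
  ids <- sprintf("S%03d", 1:n)
  tb <- stats::setNames(stats::runif(n, 0.1, 0.7), ids)
  tsl <- stats::setNames(stats::runif(n, 0, 0.1), ids)
  covs <- data.frame(age_baseline = stats::rnorm(n, 68, 10),
                     premorbid_iq = stats::rnorm(n, 100, 10),
                     sex = stats::rbinom(n, 1, 0.6), row.names = ids)
  # exact linear world, no noise
  y <- stats::setNames(0.1 - 0.05 * tb - 0.3 * tsl, ids)
  fit <- regress_slopes(y, tb, tsl, covs)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["theta_baseline", 1]), -0.05,
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["theta_slope", 1]), -0.3,
               tolerance = 1e-9)

  # null world: theta terms near zero
  set.seed(104)
  n2 <- 500
  ids2 <- sprintf("N%03d", 1:n2)
  tb2 <- stats::setNames(stats::runif(n2, 0.1, 0.7), ids2)
  ts2 <- stats::setNames(stats::runif(n2, 0, 0.1), ids2)
  covs2 <- data.frame(age_baseline = stats::rnorm(n2, 68, 10),
                      premorbid_iq = stats::rnorm(n2, 100, 10),
                      sex = stats::rbinom(n2, 1, 0.6), row.names = ids2)
  y_null <- stats::setNames(stats::rnorm(n2, 0, 0.05), ids2)
  fnull <- regress_slopes(y_null, tb2, ts2, covs2)
  co <- fnull$coefficients
  expect_lt(abs(co["theta_baseline", 1]), 3 * co["theta_baseline", 2])
  expect_lt(abs(co["theta_slope", 1]), 3 * co["theta_slope", 2])

  # generator coupling alpha1 = -0.05 per radian on baseline theta
  y_c <- stats::setNames(-0.05 * tb2 + stats::rnorm(n2, 0, 0.02), ids2)
  fc <- regress_slopes(y_c, tb2, ts2, covs2)
  expect_lt(abs(fc$coefficients["theta_baseline", 1] + 0.05),
            3 * fc$coefficients["theta_baseline", 2])

  # collinear design named in the error
  covs_bad <- covs2
  covs_bad$dup <- covs_bad$age_baseline
  covs_bad$dup <- covs_bad$dup - mean(covs_bad$dup)
  expect_error(regress_slopes(y_c, tb2, ts2, covs_bad), "collinear")
})

test_that("age is mean-centered before regression", {
  set.seed(105)
  n <- 60
  ids <- sprintf("S%03d", 1:n)
  tb <- stats::setNames(stats::runif(n, 0.1, 0.7), ids)
  tsl <- stats::setNames(stats::runif(n, 0, 0.1), ids)
  covs <- data.frame(age_baseline = stats::rnorm(n, 68, 10),
                     premorbid_iq = stats::rnorm(n, 100, 10),
                     sex = stats::rbinom(n, 1, 0.5), row.names = ids)
  y <- stats::setNames(stats::rnorm(n), ids)
  f1 <- regress_slopes(y, tb, tsl, covs)
  covs2 <- covs; covs2$age_baseline <- covs2$age_baseline + 1000
  f2 <- regress_slopes(y, tb, tsl, covs2)
  expect_equal(f1$coefficients["age_baseline", 1],
               f2$coefficients["age_baseline", 1], tolerance = 1e-9)
  expect_equal(f1$coefficients["(Intercept)", 1],
               f2$coefficients["(Intercept)", 1], tolerance = 1e-6)
})
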