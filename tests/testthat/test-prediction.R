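test_that("z-scoring standardizes and is idempotent", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- zscore_covariates(d, c("a", "b"))
  expect_equal(z$a, c(-1, 0, 1), tolerance = 1e-12)
  for (cl in c("a", "b")) {
    expect_equal(mean(z[[cl]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z[[cl]]), 1, tolerance = 1e-12)
  }
  z2 <- zscore_covariates(z, "a")
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  d$c <- 5
  expect_error(zscore_covariates(d, "c"), "zero variance.*c")
})

test_that("Cox recovers null and non-null hazards, invariant to units", {
  set.seed(201)
  n <- 500
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, 0.1)                      # independent of x
  d <- data.frame(x = x, event_time = pmin(t_ev, 5),
                  event_observed = t_ev <= 5)
  f_null <- fit_cox(d, "x")
  expect_lt(abs(f_null$table$coef), 3 * f_null$table$se)
  expect_identical(f_null$ties, "efron")

  # true HR per SD = 3.3
  set.seed(202)
  n2 <- 300
  z <- stats::rnorm(n2)
  lam <- 0.045 * exp(log(3.3) * z)
  t2 <- stats::rexp(n2, lam)
  d2 <- data.frame(x = z, event_time = pmin(t2, 5),
                   event_observed = t2 <= 5)
  d2z <- zscore_covariates(d2, "x")
  f2 <- fit_cox(d2z, "x")
  expect_gt(f2$table$hr, 2.3)
  expect_lt(f2$table$hr, 4.7)
  expect_true(f2$table$hr_lo < f2$table$hr & f2$table$hr < f2$table$hr_hi)
  expect_equal(f2$table$hr, exp(f2$table$coef), tolerance = 1e-12)

  # doubling units before z-scoring changes nothing
  d3 <- d2; d3$x <- 2 * d3$x
  f3 <- fit_cox(zscore_covariates(d3, "x"), "x")
  expect_equal(f3$table$coef, f2$table$coef, tolerance = 1e-9)

  d_none <- d2; d_none$event_observed <- FALSE
  expect_error(fit_cox(d_none, "x"), "no observed events")
})

test_that("univariate and multivariable modes fit the stated models", {
  set.seed(203)
  n <- 200
  d <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  lam <- 0.05 * exp(0.8 * d$a)
  t_ev <- stats::rexp(n, lam)
  d$event_time <- pmin(t_ev, 5); d$event_observed <- t_ev <= 5
  multi <- fit_cox(d, c("a", "b"), mode = "multivariable")
  uni <- fit_cox(d, c("a", "b"), mode = "univariate")
  expect_identical(nrow(multi$table), 2L)
  expect_identical(length(multi$models), 1L)
  expect_identical(length(uni$models), 2L)
  expect_lt(abs(multi$table$coef[1] - 0.8), 3 * multi$table$se[1])
})

test_that("LDA matches its closed forms and the MASS oracle", {
  set.seed(204)
  n <- 200
  X <- rbind(matrix(stats::rnorm(n * 2, 0), ncol = 2),
             matrix(stats::rnorm(n * 2, 8), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = n)
  m <- lda_fit(X, y)
  pr <- predict(m, X)
  expect_equal(mean(pr$label == y), 1)           # well separated
  # spherical covariance: direction parallel to the mean difference
  dmu <- m$mu1 - m$mu0
  cosang <- sum(m$w * dmu) / sqrt(sum(m$w^2) * sum(dmu^2))
  expect_gt(cosang, 0.95)

  # 1-D threshold equals the pooled-variance closed form
  set.seed(205)
  x1 <- matrix(stats::rnorm(80, 0, 1.5), ncol = 1)
  x2 <- matrix(stats::rnorm(40, 3, 1.5), ncol = 1)
  X1 <- rbind(x1, x2); y1 <- rep(c(FALSE, TRUE), c(80, 40))
  m1 <- lda_fit(X1, y1)
  s2 <- ((80 - 1) * stats::var(x1[, 1]) + (40 - 1) * stats::var(x2[, 1])) /
    (120 - 2)
  mu0 <- mean(x1); mu1 <- mean(x2)
  xstar <- (mu0 + mu1) / 2 - s2 / (mu1 - mu0) * log(m1$priors[2] / m1$priors[1])
  expect_equal(predict(m1, matrix(xstar))$score, 0, tolerance = 1e-9)
  expect_true(predict(m1, matrix(xstar + 1e-6))$label)
  expect_false(predict(m1, matrix(xstar - 1e-6))$label)

  # MASS as independent oracle for class predictions
  skip_if_not_installed("MASS")
  mo <- MASS::lda(X, grouping = factor(y))
  po <- stats::predict(mo, as.data.frame(X))
  expect_equal(as.logical(po$class == "TRUE"), pr$label)
  expect_equal(unname(po$posterior[, "TRUE"]), pr$posterior,
               tolerance = 1e-6)
})

test_that("identical class means give chance-level LOO AUC", {
  set.seed(206)
  n <- 400
  X <- matrix(stats::rnorm(n * 2), ncol = 2)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  rep_null <- loo_cv_classify(X, y)
  expect_gt(rep_null$auc, 0.4)
  expect_lt(rep_null$auc, 0.6)
})

test_that("LOO classification is pure and perfect when separable", {
  set.seed(207)
  X <- matrix(c(stats::rnorm(30, 0), stats::rnorm(30, 10)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 30)
  r <- loo_cv_classify(X, y)
  for (metric in c("sensitivity", "specificity", "accuracy", "bcr", "auc")) {
    expect_equal(r[[metric]], 1)
  }
  # permuted labels: chance AUC
  set.seed(208)
  X2 <- matrix(stats::rnorm(200), ncol = 1)
  y2 <- sample(rep(c(TRUE, FALSE), each = 100))
  r2 <- loo_cv_classify(X2, y2)
  expect_gt(r2$auc, 0.4); expect_lt(r2$auc, 0.6)

  # leakage check: flipping the held-out subject's label cannot change the
  # model its fold was scored with
  set.seed(209)
  X3 <- matrix(stats::rnorm(30), ncol = 1)
  y3 <- rep(c(TRUE, FALSE), 15)
  i <- 7
  y3_flip <- y3; y3_flip[i] <- !y3_flip[i]
  r3 <- loo_cv_classify(X3, y3)
  r3f <- loo_cv_classify(X3, y3_flip)
  expect_equal(r3f$loo_scores[i], r3$loo_scores[i], tolerance = 1e-12)
})

test_that("classification metrics satisfy their identities", {
  set.seed(210)
  for (rep in 1:20) {
    n <- 80
    y <- stats::runif(n) < 0.3
    if (!any(y) || all(y)) next
    s <- stats::rnorm(n) + y
    yhat <- s > stats::quantile(s, 0.6)
    m <- classification_metrics(y, yhat, s)
    expect_equal(m$bcr, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn), tolerance = 1e-12)
    expect_equal(m$specificity, m$tn / (m$tn + m$fp), tolerance = 1e-12)
    expect_equal(m$accuracy, (m$tp + m$tn) / n, tolerance = 1e-12)
    # AUC equals the normalized Mann-Whitney U on the scores
    u <- sum(rank(s)[y]) - sum(y) * (sum(y) + 1) / 2
    expect_equal(m$auc, u / (sum(y) * sum(!y)), tolerance = 1e-12)
  }
  # worked arithmetic: sens 0.70, spec 0.90 -> BCR 0.80
  y <- rep(c(TRUE, FALSE), c(10, 10))
  yhat <- c(rep(TRUE, 7), rep(FALSE, 3), rep(FALSE, 9), TRUE)
  m <- classification_metrics(y, yhat, seq_along(y))
  expect_equal(m$bcr, 0.8, tolerance = 1e-12)
  # degenerate score orderings
  y2 <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(classification_metrics(y2, y2, c(rep(2, 5), rep(1, 5)))$auc, 1)
  expect_equal(classification_metrics(y2, y2, rep(1, 10))$auc, 0.5)
  expect_error(classification_metrics(rep(TRUE, 4), rep(TRUE, 4), 1:4),
               "both classes")
})

test_that("onset midpoints follow the visit-bracketing convention", {
  expect_equal(onset_midpoint(3, 2), 2.5)
  expect_equal(onset_midpoint(c(2, 5), c(1, 4)), c(1.5, 4.5))
  expect_error(onset_midpoint(2, 2), "must follow")
})
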