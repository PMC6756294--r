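#' Linear mixed-effects model of annualized change
#'
#' Fits `outcome ~ time + (time | subject)` by maximum likelihood: the fixed
#' time slope is the average annualized change rate and the random intercept
#' and slope absorb inter-individual differences. The Wald statistic on the
#' time fixed effect — the squared slope z-ratio — tests the model of
#' change. The observation window honours the design asymmetry of the
#' cohort: theta is modelled on visits up to 3 years, cognition up to 5
#' (override with `max_time`).
#'
#' If the random-effects covariance is singular (or the full model fails to
#' converge), the fit falls back to a random-intercept-only model, flagged
#' in `fallback`; if even that degenerates (e.g. noise-free data), a plain
#' least-squares fit on the pooled rows is used and flagged.
#'
#' @param cohort data frame with columns `subject_id`, `visit_time` and the
#'   outcome.
#' @param outcome outcome column name (e.g. `"theta"`, `"EF"`).
#' @param max_time visit-time window; default 3 for `theta`, 5 otherwise.
#' @param reml use REML instead of ML (default FALSE).
#' @return an object of class `"lme_fit"`: `outcome`, `fixed_intercept`,
#'   `fixed_slope` (units/year), `slope_se`, `wald_stat`, `wald_p`,
#'   `ranef_sd` (named vector), `subject_slopes` (named, empirical Bayes),
#'   `fallback`, `n_subjects`, `n_obs`, `model` (the lme4 fit or NULL).
#' @export
fit_lme_change <- function(cohort, outcome,
                           max_time = if (outcome == "theta") 3 else 5,
                           reml = FALSE) {
  stopifnot(outcome %in% names(cohort))
  d <- cohort[!is.na(cohort[[outcome]]) & cohort$visit_time <= max_time,
              c("subject_id", "visit_time", outcome)]
  names(d) <- c("subject_id", "visit_time", "y")
  d$subject_id <- factor(d$subject_id)
  n_multi <- sum(table(d$subject_id) >= 2)
  if (nlevels(d$subject_id) < 2 || n_multi < 2) {
    stop("need >= 2 subjects with >= 2 visits to model change")
  }
  fallback <- "none"
  if (stats::var(d$y) < 1e-24) {           # constant outcome: no change
    return(structure(list(outcome = outcome, fixed_intercept = mean(d$y),
                          fixed_slope = 0, slope_se = 0, wald_stat = 0,
                          wald_p = 1, ranef_sd = c(intercept = 0, slope = 0),
                          subject_slopes = stats::setNames(
                            rep(0, nlevels(d$subject_id)),
                            levels(d$subject_id)),
                          fallback = "constant-outcome",
                          n_subjects = nlevels(d$subject_id),
                          n_obs = nrow(d), model = NULL),
                     class = "lme_fit"))
  }
  degenerate <- suppressWarnings(
    summary(stats::lm(y ~ visit_time, data = d))$sigma) < 1e-12
  fit <- NULL
  if (!degenerate) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ visit_time + (visit_time | subject_id), data = d,
                   REML = reml))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      fallback <- "random-intercept-only"
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(y ~ visit_time + (1 | subject_id), data = d,
                     REML = reml))),
        error = function(e) NULL)
      if (!is.null(fit) && stats::sigma(fit) < 1e-10) fit <- NULL
    }
  }
  if (is.null(fit)) {
    # fully degenerate data (e.g. zero noise): pooled OLS
    fallback <- "pooled-ols"
    ols <- stats::lm(y ~ visit_time, data = d)
    co <- suppressWarnings(summary(ols))$coefficients
    slope <- co["visit_time", "Estimate"]
    se <- co["visit_time", "Std. Error"]
    subj <- stats::setNames(rep(slope, nlevels(d$subject_id)),
                            levels(d$subject_id))
    if (!is.finite(se)) se <- 0
    wald <- if (se > 0) (slope / se)^2
            else if (abs(slope) < 1e-12) 0 else Inf
    return(structure(list(outcome = outcome,
                          fixed_intercept = co["(Intercept)", "Estimate"],
                          fixed_slope = slope, slope_se = se,
                          wald_stat = wald,
                          wald_p = stats::pchisq(wald, 1, lower.tail = FALSE),
                          ranef_sd = c(intercept = 0, slope = 0),
                          subject_slopes = subj, fallback = fallback,
                          n_subjects = nlevels(d$subject_id),
                          n_obs = nrow(d), model = NULL),
                     class = "lme_fit"))
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["visit_time"]]
  slope <- fe[["visit_time"]]
  wald <- (slope / se)^2
  re <- lme4::ranef(fit)$subject_id
  subj_slope <- if ("visit_time" %in% colnames(re)) {
    slope + re[, "visit_time"]
  } else {
    rep(slope, nrow(re))
  }
  sds <- c(intercept = vc$sdcor[vc$grp == "subject_id" &
                                  vc$var1 == "(Intercept)" & is.na(vc$var2)][1],
           slope = if (any(vc$var1 == "visit_time" & is.na(vc$var2), na.rm = TRUE))
             vc$sdcor[which(vc$var1 == "visit_time" & is.na(vc$var2))[1]] else 0,
           residual = vc$sdcor[vc$grp == "Residual"][1])
  structure(list(outcome = outcome, fixed_intercept = fe[["(Intercept)"]],
                 fixed_slope = slope, slope_se = se, wald_stat = wald,
                 wald_p = stats::pchisq(wald, 1, lower.tail = FALSE),
                 ranef_sd = sds,
                 subject_slopes = stats::setNames(subj_slope, rownames(re)),
                 fallback = fallback, n_subjects = nlevels(d$subject_id),
                 n_obs = nrow(d), model = fit),
            class = "lme_fit")
}

#' Per-subject annualized slopes from a mixed model
#'
#' Empirical-Bayes (shrunken) subject slopes: the fixed time slope plus each
#' subject's predicted random slope. Under a random-intercept-only fallback
#' all subjects share the fixed slope.
#'
#' @param fit an [fit_lme_change()] result.
#' @return named numeric vector of slopes, one per subject.
#' @export
extract_subject_slopes <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  fit$subject_slopes
}

#' Per-subject ordinary-least-squares slopes
#'
#' Unshrunken alternative to the empirical-Bayes slopes of
#' [extract_subject_slopes()]: an independent straight line per subject.
#' Used when the mixed model degenerates to a random-intercept-only fit
#' (every EB slope then equals the fixed slope and carries no
#' between-subject signal).
#'
#' @param cohort data frame with `subject_id`, `visit_time`, the outcome.
#' @param outcome outcome column name.
#' @param max_time visit window (default as in [fit_lme_change()]).
#' @return named numeric vector; NA for subjects with < 2 usable visits.
#' @export
subject_ols_slopes <- function(cohort, outcome,
                               max_time = if (outcome == "theta") 3 else 5) {
  d <- cohort[!is.na(cohort[[outcome]]) & cohort$visit_time <= max_time, ]
  vapply(split(d, d$subject_id), function(s) {
    if (nrow(s) < 2 || stats::var(s$visit_time) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(s[[outcome]] ~ s$visit_time))[2])
  }, numeric(1))
}

#' Regress cognitive slopes on baseline theta and theta change
#'
#' Second stage of the two-stage change analysis (the theta and cognition
#' observation windows differ, so their joint trajectory is not modelled
#' directly): ordinary least squares of per-subject cognitive slopes on
#' baseline theta and theta slope, adjusted for mean-centered baseline age,
#' premorbid IQ and sex.
#'
#' @param cog_slopes named vector of per-subject cognitive slopes.
#' @param theta_baseline named vector of baseline theta (radians).
#' @param theta_slopes named vector of per-subject theta slopes.
#' @param covariates data frame with rownames = subject ids and columns
#'   `age_baseline`, `premorbid_iq`, `sex` (others are carried through).
#' @param outcome_name label stored on the fit.
#' @return an object of class `"slope_regression"`: `coefficients` (matrix
#'   with estimate/se/t/p), `r_squared`, `n`, `model`.
#' @export
regress_slopes <- function(cog_slopes, theta_baseline, theta_slopes,
                           covariates, outcome_name = "cognitive_slope") {
  ids <- Reduce(intersect, list(names(cog_slopes), names(theta_baseline),
                                names(theta_slopes), rownames(covariates)))
  if (length(ids) < 3) stop("fewer than 3 subjects common to all inputs")
  d <- data.frame(y = cog_slopes[ids],
                  theta_baseline = theta_baseline[ids],
                  theta_slope = theta_slopes[ids],
                  covariates[ids, , drop = FALSE])
  if ("age_baseline" %in% names(d)) {
    d$age_baseline <- d$age_baseline - mean(d$age_baseline)
  }
  X <- stats::model.matrix(y ~ ., data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = d)
  sm <- suppressWarnings(summary(fit))   # noise-free inputs fit perfectly
  structure(list(outcome = outcome_name, coefficients = sm$coefficients,
                 r_squared = sm$r.squared, n = nrow(d), model = fit),
            class = "slope_regression")
}
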