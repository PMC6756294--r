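#' Z-score transform covariate columns
#'
#' Standardizes the named continuous columns to full-sample mean 0 and SD 1
#' (sample SD), recording the transform parameters so the same scaling can
#' be replayed.
#'
#' @param cohort data frame.
#' @param names columns to transform.
#' @return the transformed data frame; attribute `"zscore_params"` holds a
#'   data frame of means and SDs.
#' @export
zscore_covariates <- function(cohort, names) {
  stopifnot(all(names %in% colnames(cohort)))
  params <- data.frame(column = names, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(names)) {
    x <- cohort[[names[i]]]
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero variance in column: ", names[i])
    }
    cohort[[names[i]]] <- (x - m) / s
    params$mean[i] <- m; params$sd[i] <- s
  }
  attr(cohort, "zscore_params") <- params
  cohort
}

#' Cox proportional-hazards model of conversion risk
#'
#' Partial-likelihood Cox regression of conversion to dementia on baseline
#' covariates, Efron ties handling. `mode = "univariate"` fits one model per
#' covariate; `mode = "multivariable"` fits them jointly (the variables
#' significant there feed the discriminant analysis).
#'
#' @param cohort one row per subject with `event_time` (years, onset or
#'   censoring) and `event_observed` (logical), plus covariates.
#' @param covariates covariate column names.
#' @param mode `"multivariable"` (default) or `"univariate"`.
#' @return an object of class `"cox_fit"`: `table` (data frame with `coef`,
#'   `hr`, `hr_lo`, `hr_hi`, `se`, `p` per covariate), `n_events`, `ties`,
#'   `mode`, `models`.
#' @export
fit_cox <- function(cohort, covariates,
                    mode = c("multivariable", "univariate")) {
  mode <- match.arg(mode)
  stopifnot(all(covariates %in% colnames(cohort)))
  if (sum(cohort$event_observed) < 1) stop("no observed events")
  if (any(cohort$event_time <= 0)) stop("event_time must be positive")
  notes <- character(0)
  fit_one <- function(vars) {
    f <- stats::as.formula(paste("survival::Surv(event_time, event_observed) ~",
                                 paste(vars, collapse = " + ")))
    # monotone-likelihood / iteration warnings at small n are recorded on
    # the fit rather than emitted
    withCallingHandlers(
      survival::coxph(f, data = cohort, ties = "efron"),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  if (mode == "multivariable") {
    models <- list(fit_one(covariates))
  } else {
    models <- lapply(covariates, fit_one)
  }
  rows <- do.call(rbind, lapply(models, function(m) {
    sm <- summary(m)
    data.frame(covariate = rownames(sm$coefficients),
               coef = sm$coefficients[, "coef"],
               hr = sm$conf.int[, "exp(coef)"],
               hr_lo = sm$conf.int[, "lower .95"],
               hr_hi = sm$conf.int[, "upper .95"],
               se = sm$coefficients[, "se(coef)"],
               p = sm$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }))
  structure(list(table = rows, n_events = sum(cohort$event_observed),
                 ties = "efron", mode = mode, models = models,
                 notes = notes),
            class = "cox_fit")
}

#' Two-class linear discriminant analysis
#'
#' Gaussian LDA with pooled within-class covariance: class priors default to
#' the empirical proportions (they matter under the cohort's 18/99
#' imbalance; set `priors` for equal weighting) and classification
#' thresholds the posterior at 0.5. A ridge `1e-8 * mean(diag)` is added if
#' the pooled covariance is singular, flagged in `ridged`.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive (converter)
#'   class.
#' @param priors optional length-2 vector `(negative, positive)` summing
#'   to 1.
#' @return an object of class `"dseg_lda"` with the pooled-covariance
#'   discriminant direction, class means, priors and intercept.
#' @export
lda_fit <- function(features, labels, priors = NULL) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  if (any(is.na(y)) || length(y) != nrow(X)) stop("bad labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n0 < 2 || n1 < 2) stop("need >= 2 subjects per class")
  mu0 <- colMeans(X[!y, , drop = FALSE])
  mu1 <- colMeans(X[y, , drop = FALSE])
  S0 <- stats::cov(X[!y, , drop = FALSE])
  S1 <- stats::cov(X[y, , drop = FALSE])
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  if (is.null(priors)) priors <- c(n0, n1) / (n0 + n1)
  ridged <- FALSE
  w <- tryCatch(solve(Sp, mu1 - mu0), error = function(e) NULL)
  if (is.null(w)) {
    ridged <- TRUE
    Sp <- Sp + diag(1e-8 * mean(diag(Sp)) + 1e-12, ncol(Sp))
    w <- solve(Sp, mu1 - mu0)
  }
  # decision: w'x + b > 0 classifies positive at posterior 0.5
  b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[2] / priors[1])
  structure(list(w = w, b = b, mu0 = mu0, mu1 = mu1, Sp = Sp,
                 priors = priors, ridged = ridged,
                 feature_names = colnames(X)),
            class = "dseg_lda")
}

#' Score and classify with a fitted LDA model
#'
#' @param object a [lda_fit()] model.
#' @param newdata numeric matrix of features.
#' @param ... unused.
#' @return data frame with `score` (the linear discriminant score
#'   `w'x + b`; positive favours the converter class), `posterior`
#'   (positive-class posterior) and `label` (logical prediction at
#'   posterior 0.5).
#' @export
predict.dseg_lda <- function(object, newdata, ...) {
  X <- matrix(as.numeric(as.matrix(newdata)), ncol = length(object$w))
  score <- as.numeric(X %*% object$w + object$b)
  data.frame(score = score, posterior = stats::plogis(score),
             label = score > 0)
}

#' Leave-one-out cross-validated classification
#'
#' For each subject the discriminant is refitted on the remaining n-1 and
#' the held-out subject scored; the report is built solely from held-out
#' scores and predictions, so it reflects model stability rather than
#' training fit. Folds whose training set loses a class are flagged,
#' skipped, and counted in `n_skipped_folds`.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels logical or 0/1 vector; `TRUE` is the converter class.
#' @param priors optional fixed priors passed to every fold's [lda_fit()].
#' @return a `"classification_report"` (see [classification_metrics()])
#'   with additional fields `loo_scores`, `loo_labels` (predictions) and
#'   `n_skipped_folds`.
#' @export
loo_cv_classify <- function(features, labels, priors = NULL) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects for leave-one-out")
  scores <- rep(NA_real_, n)
  preds <- rep(NA, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2 || sum(ytr) < 2 || sum(!ytr) < 2) {
      skipped <- skipped + 1L
      next
    }
    m <- lda_fit(X[-i, , drop = FALSE], ytr, priors = priors)
    pr <- predict(m, X[i, , drop = FALSE])
    scores[i] <- pr$score
    preds[i] <- pr$label
  }
  ok <- !is.na(scores)
  rep_out <- classification_metrics(labels = y[ok], predicted = preds[ok],
                                    scores = scores[ok])
  rep_out$loo_scores <- scores
  rep_out$loo_labels <- preds
  rep_out$n_skipped_folds <- skipped
  rep_out
}

#' Classification metrics from held-out predictions
#'
#' Confusion counts, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/n`, the balanced classification rate
#' `BCR = (sensitivity + specificity)/2` — the preferred summary under
#' class imbalance — and the AUC (C statistic) from the ROC of the scores,
#' computed by the trapezoidal rule with midrank tie handling (equal to the
#' normalized Mann-Whitney U statistic).
#'
#' @param labels logical vector of true classes (`TRUE` = converter).
#' @param predicted logical vector of predicted classes.
#' @param scores numeric classifier scores (larger = more converter-like).
#' @return an object of class `"classification_report"`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `bcr`, `auc`, `n`.
#' @export
classification_metrics <- function(labels, predicted, scores) {
  y <- as.logical(labels); yhat <- as.logical(predicted)
  stopifnot(length(y) == length(yhat), length(y) == length(scores))
  if (!any(y) || all(y)) {
    stop("both classes required: sensitivity/specificity undefined")
  }
  tp <- sum(y & yhat); fn <- sum(y & !yhat)
  tn <- sum(!y & !yhat); fp <- sum(!y & yhat)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(y),
                 bcr = (sens + spec) / 2,
                 auc = roc_auc(scores, y), n = length(y)),
            class = "classification_report")
}

#' ROC curve and trapezoidal AUC
#'
#' ROC over the unique score thresholds (ties grouped, giving the midrank
#' handling that makes the trapezoidal area equal the normalized
#' Mann-Whitney U statistic).
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels logical vector.
#' @return `roc_points()`: data frame of (fpr, tpr) from (0,0) to (1,1).
#'   `roc_auc()`: scalar area.
#' @export
roc_points <- function(scores, labels) {
  y <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!y)), tpr = c(0, tp[last] / sum(y)))
}

#' @rdname roc_points
#' @export
roc_auc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Dementia onset time by the midpoint convention
#'
#' When a diagnosis is established at a follow-up visit, onset is dated to
#' the midpoint between that visit and the previous attended visit (or to
#' the clinical diagnosis date when one exists).
#'
#' @param diagnosis_visit visit time (years) at which diagnosis was
#'   established.
#' @param previous_visit time of the previous attended visit.
#' @return onset time in years.
#' @export
onset_midpoint <- function(diagnosis_visit, previous_visit) {
  if (any(diagnosis_visit <= previous_visit)) {
    stop("diagnosis visit must follow the previous visit")
  }
  (diagnosis_visit + previous_visit) / 2
}
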