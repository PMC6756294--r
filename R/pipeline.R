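# FNV-1a hash of a deparsed object; cheap provenance fingerprint for the
# run manifest (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end: cohort generation, phantom imaging,
#' (p,q) maps, pooled histogram, 16-segment k-medians fit (pooled across
#' patients and healthy controls, as the segmentation is defined), per-scan
#' segment assignment and spectra, reference selection from the healthy
#' pool, theta scoring, linear mixed-effects change models, slope
#' regressions for the declining domains, Cox conversion models, and
#' leave-one-out discriminant classification. With `imaging = "latent"`
#' the imaging stages are skipped and the generator's latent theta stands
#' in (fast path for statistical studies).
#'
#' @param config a [synthetic_config()].
#' @param imaging `"phantom"` (default) or `"latent"`.
#' @param n_bins histogram bins per axis (default `c(256, 256)`).
#' @param lda_priors optional fixed LDA priors `(stable, converter)`.
#' @return list of class `"dseg_run"`: `cohort`, `truth`, `model`
#'   (phantom mode), `reference_id`, `theta` (per-scan table), `lme` (named
#'   list of [fit_lme_change()] fits), `slope_regressions`, `cox_univariate`,
#'   `cox_multivariable`, `lda` (named list of classification reports),
#'   `subject_table` (one row per subject with the discriminant features),
#'   `manifest` (stages, config hash, seed, counts).
#' @export
run_dseg_pipeline <- function(config, imaging = c("phantom", "latent"),
                              n_bins = c(256L, 256L), lda_priors = NULL) {
  imaging <- match.arg(imaging)
  stages <- character(0)
  t0 <- Sys.time()
  gen <- generate_cohort(config, imaging = imaging)
  stages <- c(stages, "generate_cohort")
  cohort <- gen$cohort
  model <- NULL; ref <- NULL; theta_tab <- NULL
  n_pooled <- NA_integer_
  if (imaging == "phantom") {
    healthy <- generate_healthy_scans(config)
    pq_healthy <- lapply(healthy, compute_pq)
    pq_patient <- lapply(gen$scans, compute_pq)
    stages <- c(stages, "compute_pq")
    hist <- build_pq_histogram(c(pq_healthy, pq_patient), n_bins = n_bins)
    n_pooled <- hist$n_total
    model <- kmedians_fit(hist, k = 16L)
    stages <- c(stages, "kmedians_fit")
    spec_of <- function(pq, key) {
      parts <- strsplit(key, "_t")[[1]]
      compute_spectrum(assign_segments(pq, model), subject_id = parts[1],
                       visit_time = as.numeric(parts[2]))
    }
    healthy_spectra <- mapply(spec_of, pq_healthy, names(pq_healthy),
                              SIMPLIFY = FALSE)
    patient_spectra <- mapply(spec_of, pq_patient, names(pq_patient),
                              SIMPLIFY = FALSE)
    stages <- c(stages, "spectra")
    ref <- select_reference(unname(healthy_spectra))
    theta_tab <- theta_series(unname(patient_spectra), ref)
    stages <- c(stages, "theta")
    cohort$theta <- NULL
    cohort <- merge(cohort, stats::setNames(
      theta_tab[, c("subject_id", "visit_time", "theta_rad")],
      c("subject_id", "visit_time", "theta")),
      by = c("subject_id", "visit_time"), all.x = TRUE)
    cohort <- cohort[order(cohort$subject_id, cohort$visit_time), ]
  }

  lme <- list()
  for (oc in c("theta", "EF", "IPS", "WkM", "EM", "GC")) {
    lme[[oc]] <- fit_lme_change(cohort, oc)
  }
  stages <- c(stages, "lme")

  base <- cohort[cohort$visit_time == 0, ]
  theta_b <- stats::setNames(base$theta, base$subject_id)
  theta_sl <- extract_subject_slopes(lme$theta)
  if (stats::sd(theta_sl) < 1e-10) {
    # degenerate EB slopes (random-intercept fallback): use per-subject OLS
    theta_sl <- subject_ols_slopes(cohort, "theta")
  }
  covs <- base[, c("age_baseline", "premorbid_iq", "sex")]
  rownames(covs) <- base$subject_id
  constant_covs <- names(covs)[vapply(covs, function(x) {
    stats::sd(x) == 0
  }, logical(1))]
  covs <- covs[, setdiff(names(covs), constant_covs), drop = FALSE]

  declining <- names(Filter(function(f) f$wald_p < 0.05 && f$fixed_slope < 0,
                            lme[c("EF", "IPS", "WkM", "EM", "GC")]))
  slope_reg <- lapply(declining, function(oc) {
    regress_slopes(extract_subject_slopes(lme[[oc]]), theta_b, theta_sl,
                   covs, outcome_name = paste0(oc, "_slope"))
  })
  names(slope_reg) <- declining
  stages <- c(stages, "slope_regressions")

  subj <- data.frame(subject_id = base$subject_id,
                     theta_baseline = theta_b[base$subject_id],
                     theta_slope = theta_sl[base$subject_id],
                     age_baseline = base$age_baseline,
                     premorbid_iq = base$premorbid_iq, sex = base$sex,
                     event_time = base$event_time,
                     event_observed = base$event_observed)
  subj <- subj[stats::complete.cases(subj), ]
  zsubj <- zscore_covariates(subj, c("theta_baseline", "theta_slope",
                                     "age_baseline", "premorbid_iq"))
  feat_cols <- setdiff(c("theta_baseline", "theta_slope", "age_baseline",
                         "premorbid_iq", "sex"), constant_covs)
  cox_uni <- fit_cox(zsubj, feat_cols, mode = "univariate")
  cox_multi <- fit_cox(zsubj, c("theta_baseline", "theta_slope"),
                       mode = "multivariable")
  stages <- c(stages, "cox")

  y <- subj$event_observed
  feats <- as.matrix(zsubj[, feat_cols])
  try_loo <- function(x) {
    # infeasible with too few events (tiny cohorts); recorded, not fatal
    tryCatch(loo_cv_classify(x, y, priors = lda_priors),
             error = function(e) NULL)
  }
  lda <- list(
    theta_baseline = try_loo(feats[, "theta_baseline", drop = FALSE]),
    theta_change = try_loo(feats[, "theta_slope", drop = FALSE]),
    combined = try_loo(feats))
  stages <- c(stages, "lda")

  structure(list(
    cohort = cohort, truth = gen$truth, model = model,
    reference_id = if (!is.null(ref)) ref$reference_id else NA_character_,
    theta = theta_tab, lme = lme, slope_regressions = slope_reg,
    cox_univariate = cox_uni, cox_multivariable = cox_multi, lda = lda,
    subject_table = subj,
    manifest = list(stages = stages, config_hash = config_hash(config),
                    seed = config$rng_seed, imaging = imaging,
                    dropped_constant_covariates = constant_covs,
                    n_voxels_pooled = n_pooled,
                    n_subjects = length(unique(cohort$subject_id)),
                    n_events = sum(base$event_observed),
                    started = format(t0), finished = format(Sys.time()))),
    class = "dseg_run")
}

report_as_list <- function(run) {
  lme_tab <- lapply(run$lme, function(f) {
    list(outcome = f$outcome, fixed_slope = f$fixed_slope,
         slope_se = f$slope_se, wald_stat = f$wald_stat, wald_p = f$wald_p,
         fallback = f$fallback)
  })
  reg_tab <- lapply(run$slope_regressions, function(f) {
    co <- f$coefficients
    list(outcome = f$outcome, r_squared = f$r_squared, n = f$n,
         terms = rownames(co), estimate = unname(co[, 1]),
         p = unname(co[, 4]))
  })
  lda_tab <- lapply(Filter(Negate(is.null), run$lda), function(r) {
    r[c("tp", "fp", "tn", "fn", "sensitivity", "specificity", "accuracy",
        "bcr", "auc", "n")]
  })
  list(manifest = run$manifest,
       reference_id = run$reference_id,
       lme = lme_tab,
       slope_regressions = reg_tab,
       cox_univariate = run$cox_univariate$table,
       cox_multivariable = run$cox_multivariable$table,
       lda = lda_tab)
}

render_report_text <- function(rep) {
  ref_id <- if (is.null(rep$reference_id) || is.na(rep$reference_id)) {
    "NA"
  } else rep$reference_id
  out <- c(sprintf("dseg run %s (seed %s, imaging %s)",
                   rep$manifest$config_hash, rep$manifest$seed,
                   rep$manifest$imaging),
           sprintf("subjects %s, events %s, reference %s",
                   rep$manifest$n_subjects, rep$manifest$n_events, ref_id),
           "", "Annualized change (LME):")
  for (f in rep$lme) {
    out <- c(out, sprintf("  %-6s slope %+.4f (se %.4f)  Wald %.2f  p %.3g",
                          f$outcome, f$fixed_slope, f$slope_se, f$wald_stat,
                          f$wald_p))
  }
  if (length(rep$slope_regressions)) {
    out <- c(out, "", "Slope regressions (baseline theta + change):")
    for (f in rep$slope_regressions) {
      out <- c(out, sprintf("  %-10s R2 %.3f (n=%d)", f$outcome,
                            f$r_squared, f$n))
    }
  }
  ct <- as.data.frame(rep$cox_multivariable)
  out <- c(out, "", "Cox (multivariable, z-scored):")
  for (i in seq_len(nrow(ct))) {
    out <- c(out, sprintf("  %-16s HR %.3f (95%% CI %.3f-%.3f)  p %.3g",
                          ct$covariate[i], ct$hr[i], ct$hr_lo[i],
                          ct$hr_hi[i], ct$p[i]))
  }
  if (length(rep$lda)) {
    out <- c(out, "", "LOO-CV discriminant classification:")
    for (nm in names(rep$lda)) {
      r <- rep$lda[[nm]]
      out <- c(out, sprintf(
        "  %-16s sens %.3f spec %.3f acc %.3f BCR %.3f AUC %.3f",
        nm, r$sensitivity, r$specificity, r$accuracy, r$bcr, r$auc))
    }
  }
  paste(out, collapse = "\n")
}

#' Write the run report
#'
#' Serialises the headline results of a [run_dseg_pipeline()] run — change
#' models, slope regressions, Cox hazard ratios, classification metrics —
#' as machine-readable JSON plus a human-readable text summary rendered
#' from the same structure (so regenerating the text from the JSON
#' reproduces it exactly).
#'
#' @param run a `dseg_run` (or a report list from a previous JSON).
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>.txt`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_report <- function(run, path_prefix) {
  rep <- if (inherits(run, "dseg_run")) report_as_list(run) else run
  json_path <- paste0(path_prefix, ".json")
  txt_path <- paste0(path_prefix, ".txt")
  jsonlite::write_json(rep, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  writeLines(render_report_text(rep), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

#' Re-render the text report from a JSON report
#'
#' @param json_path path written by [write_report()].
#' @return the report text, invisibly; also returned as a character scalar.
#' @export
render_report_from_json <- function(json_path) {
  rep <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  render_report_text(rep)
}
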