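#' Synthetic cohort configuration
#'
#' Describes the simulated world: a longitudinal small-vessel-disease cohort
#' with annual imaging for 3 years and cognitive testing for 5, phantom
#' brains built from four tissue compartments (GM, WM, CSF, periventricular
#' WMH), monotone disease progression, cognitive slopes linearly coupled to
#' the latent theta trajectory, and dementia conversion driven by baseline
#' theta with the onset-date midpoint convention. Defaults target the
#' published cohort design: 99 subjects and an expected conversion fraction
#' of about 0.18 (18/99), with a true hazard ratio of 3.331 per SD of
#' baseline theta.
#'
#' Tissue eigenvalue means are generator conventions chosen so the four
#' tissues occupy distinct regions of the (p,q) plane; they are not
#' estimates of any clinical cohort.
#'
#' @param n_subjects patients (default 99).
#' @param n_healthy healthy reference pool size (default 20).
#' @param visit_times_imaging,visit_times_cognition visit grids in years.
#' @param grid_size phantom grid (default 32^3), `voxel_size` in mm.
#' @param tissue_means list of eigenvalue mean triplets (mm^2/s) for
#'   `csf`, `wm`, `gm`, `wmh`.
#' @param tissue_sd per-eigenvalue jitter SD (mm^2/s).
#' @param severity_shape1,severity_shape2 Beta parameters of baseline
#'   severity in `[0,1]`.
#' @param progression_mean,progression_sd per-year severity increase
#'   (truncated at 0 so progression is monotone).
#' @param wmh_max_frac WM fraction converted to WMH at severity 1.
#' @param theta0,theta_gain,theta_meas_sd latent-theta map
#'   `theta = theta0 + theta_gain * severity` (radians) and measurement
#'   noise used by the tabular (`imaging = "latent"`) mode.
#' @param alpha0,alpha1,alpha2 per-domain cognitive slope model
#'   `slope = alpha0 + alpha1 * theta_b + alpha2 * dtheta + noise`
#'   (z-units/year; alpha1, alpha2 per radian). WkM and EM default to zero
#'   mean slope and zero coupling.
#' @param slope_noise_sd,visit_noise_sd,baseline_sd,baseline_coupling
#'   cognitive noise SDs (z-units) and baseline coupling per SD of baseline
#'   theta.
#' @param target_event_fraction expected fraction converting (default
#'   0.18); the baseline hazard is calibrated to it.
#' @param log_hr_per_sd true log hazard ratio per SD of baseline theta
#'   (default `log(3.331)`).
#' @param log_hr_per_sd_dtheta optional additional log hazard ratio per SD
#'   of latent theta change (default 0: conversion driven by baseline
#'   severity only; set positive for a cohort whose progression also drives
#'   conversion).
#' @param dropout_rate exponential dropout rate per year.
#' @param age_mean,age_sd,age_range,male_fraction,iq_mean,iq_sd
#'   demographics.
#' @param rng_seed base seed; every stochastic stage derives from it.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_subjects = 99L, n_healthy = 20L,
    visit_times_imaging = 0:3, visit_times_cognition = 0:5,
    grid_size = c(32L, 32L, 32L), voxel_size = c(2.5, 2.5, 2.5),
    tissue_means = list(csf = c(3.0, 3.0, 3.0) * 1e-3,
                        wm  = c(1.7, 0.4, 0.3) * 1e-3,
                        gm  = c(1.1, 0.9, 0.8) * 1e-3,
                        wmh = c(1.4, 1.0, 0.9) * 1e-3),
    tissue_sd = 5e-5,
    severity_shape1 = 2, severity_shape2 = 5,
    progression_mean = 0.06, progression_sd = 0.03,
    wmh_max_frac = 0.35,
    theta0 = 0.15, theta_gain = 0.5, theta_meas_sd = 0.01,
    alpha0 = c(EF = -0.02, IPS = -0.02, WkM = 0, EM = 0),
    alpha1 = c(EF = -0.12, IPS = -0.08, WkM = 0, EM = 0),
    alpha2 = c(EF = -0.30, IPS = -0.15, WkM = 0, EM = 0),
    slope_noise_sd = 0.03, visit_noise_sd = 0.15,
    baseline_sd = 0.3, baseline_coupling = -0.3,
    target_event_fraction = 0.18, log_hr_per_sd = log(3.331),
    log_hr_per_sd_dtheta = 0,
    dropout_rate = 0.04,
    age_mean = 68.4, age_sd = 10, age_range = c(43, 88),
    male_fraction = 65 / 99, iq_mean = 100, iq_sd = 10,
    rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$tissue_sd >= 0, cfg$slope_noise_sd >= 0,
            cfg$visit_noise_sd >= 0, cfg$theta_meas_sd >= 0,
            all(diff(cfg$visit_times_imaging) > 0),
            all(diff(cfg$visit_times_cognition) > 0),
            cfg$target_event_fraction > 0, cfg$target_event_fraction < 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build a phantom brain for one subject-visit
#'
#' Nested-ellipsoid phantom: a central CSF ventricle, a WM core, a GM
#' shell, and periventricular WMH voxels carved from the WM voxels nearest
#' the ventricle. The WMH voxel count scales linearly with the subject's
#' severity at the visit (`round(severity * wmh_max_frac * n_wm)`), so a
#' severity of zero yields zero lesion voxels and monotone severity yields
#' monotone lesion load. Per-voxel eigenvalues are the tissue means plus
#' seeded Gaussian jitter, sorted descending and clamped at zero.
#'
#' @param config a [synthetic_config()].
#' @param severity disease severity in `[0, 1]` at this visit.
#' @param seed integer seed making the volume reproducible.
#' @return an [eigenvalue_volume()]; attribute `"tissue"` holds the
#'   per-voxel tissue label array (0 outside brain).
#' @export
make_phantom <- function(config, severity, seed) {
  g <- config$grid_size
  if (any(g < 8)) stop("grid too small to contain all compartments")
  stopifnot(severity >= -1e-12, severity <= 1 + 1e-12)
  severity <- min(max(severity, 0), 1)
  ax <- lapply(g, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  u2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r <- sqrt(u2) / 0.9                       # 1 at the brain surface
  mask <- r <= 1
  tissue <- array(0L, g)                    # 1 csf, 2 wm, 3 gm, 4 wmh
  tissue[mask & r > 0.75] <- 3L
  tissue[mask & r <= 0.75] <- 2L
  tissue[mask & r <= 0.3] <- 1L
  wm_idx <- which(tissue == 2L)
  n_wmh <- round(severity * config$wmh_max_frac * length(wm_idx))
  if (n_wmh > 0) {
    # carve WMH from the WM voxels closest to the ventricle surface,
    # breaking radius ties deterministically by voxel index
    o <- order(r[wm_idx], wm_idx)
    tissue[wm_idx[o[seq_len(n_wmh)]]] <- 4L
  }
  means <- rbind(config$tissue_means$csf, config$tissue_means$wm,
                 config$tissue_means$gm, config$tissue_means$wmh)
  idx <- which(tissue > 0L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  lam <- means[tissue[idx], , drop = FALSE] +
    matrix(stats::rnorm(3 * length(idx), 0, config$tissue_sd), ncol = 3)
  lam[lam < 0] <- 0
  hi <- pmax(lam[, 1], lam[, 2], lam[, 3])
  lo <- pmin(lam[, 1], lam[, 2], lam[, 3])
  lam <- cbind(hi, rowSums(lam) - hi - lo, lo)
  lam_arr <- array(0, c(g, 3))
  for (j in 1:3) {
    slice <- array(0, g)
    slice[idx] <- lam[, j]
    lam_arr[, , , j] <- slice
  }
  out <- eigenvalue_volume(lam_arr, tissue > 0L, config$voxel_size)
  attr(out, "tissue") <- tissue
  out
}

# Severity trajectory: monotone, capped at 1.
severity_at <- function(s0, rate, t) pmin(1, s0 + rate * t)

# Sample z-score that degrades gracefully for n = 1 or zero spread.
safe_z <- function(x) {
  s <- stats::sd(x)
  if (length(x) < 2 || !is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate cognitive composites coupled to the theta trajectory
#'
#' Per-domain annualized slopes follow
#' `alpha0 + alpha1 * theta_baseline + alpha2 * dtheta + N(0, sd^2)`; visit
#' values are `baseline + slope * t` plus visit noise, with baselines
#' coupled to baseline theta so converters are worse at study entry. WkM
#' and EM have zero mean slope and zero coupling, mirroring domains that do
#' not decline. GC is the mean of the four domain values at each visit.
#'
#' @param config a [synthetic_config()].
#' @param truth per-subject data frame with `subject_id`,
#'   `theta_latent_baseline`, `dtheta_latent`.
#' @return list: `visits` (long data frame subject x cognition visit with
#'   EF, IPS, WkM, EM, GC) and `slopes` (per-subject true slopes).
#' @export
simulate_cognition <- function(config, truth) {
  n <- nrow(truth)
  domains <- c("EF", "IPS", "WkM", "EM")
  zb <- safe_z(truth$theta_latent_baseline)
  slopes <- vapply(domains, function(d) {
    config$alpha0[[d]] +
      config$alpha1[[d]] * truth$theta_latent_baseline +
      config$alpha2[[d]] * truth$dtheta_latent +
      stats::rnorm(n, 0, config$slope_noise_sd)
  }, numeric(n))
  baselines <- vapply(domains, function(d) {
    config$baseline_coupling * zb + stats::rnorm(n, 0, config$baseline_sd)
  }, numeric(n))
  slopes <- matrix(slopes, nrow = n, dimnames = list(NULL, domains))
  baselines <- matrix(baselines, nrow = n, dimnames = list(NULL, domains))
  visits <- do.call(rbind, lapply(config$visit_times_cognition, function(t) {
    vals <- baselines + slopes * t +
      matrix(stats::rnorm(n * 4, 0, config$visit_noise_sd), n, 4)
    data.frame(subject_id = truth$subject_id, visit_time = t,
               EF = vals[, 1], IPS = vals[, 2], WkM = vals[, 3],
               EM = vals[, 4], GC = rowMeans(vals))
  }))
  list(visits = visits[order(visits$subject_id, visits$visit_time), ],
       slopes = data.frame(subject_id = truth$subject_id, slopes))
}

#' Simulate conversion to dementia
#'
#' Exponential event times with subject hazard
#' `baseline_hazard * exp(log_hr_per_sd * z(theta_baseline))`. The baseline
#' hazard is calibrated by root-finding so the expected observed-event
#' fraction matches `target_event_fraction` given each subject's censoring
#' time (administrative censoring at the last cognition visit plus random
#' dropout). Observed onsets are snapped to the midpoint between the visit
#' at which the diagnosis would be established and the previous visit;
#' censored subjects carry their last attended visit time.
#'
#' @param config a [synthetic_config()].
#' @param truth per-subject data frame with `theta_latent_baseline`.
#' @return data frame: `subject_id`, `event_time`, `event_observed`,
#'   `true_event_time` (pre-censoring), `censor_time`.
#' @export
simulate_conversion <- function(config, truth) {
  n <- nrow(truth)
  z <- safe_z(truth$theta_latent_baseline)
  rel_hazard <- exp(config$log_hr_per_sd * z)
  if (config$log_hr_per_sd_dtheta != 0) {
    rel_hazard <- rel_hazard *
      exp(config$log_hr_per_sd_dtheta * safe_z(truth$dtheta_latent))
  }
  t_max <- max(config$visit_times_cognition)
  drop_t <- if (config$dropout_rate > 0) {
    stats::rexp(n, config$dropout_rate)
  } else rep(Inf, n)
  visits <- config$visit_times_cognition
  late <- visits[visits > 0]
  last_attended <- vapply(pmin(t_max, drop_t), function(ti) {
    att <- late[late <= ti]
    if (length(att)) max(att) else min(late)   # everyone reaches visit 1
  }, numeric(1))
  target <- config$target_event_fraction
  lam0 <- stats::uniroot(function(l0) {
    mean(1 - exp(-l0 * rel_hazard * last_attended)) - target
  }, c(1e-8, 10), tol = 1e-10)$root
  true_t <- stats::rexp(n, rate = lam0 * rel_hazard)
  observed <- true_t <= last_attended
  event_time <- last_attended
  if (any(observed)) {
    dx_visit <- vapply(true_t[observed], function(tt) min(late[late >= tt]),
                       numeric(1))
    prev <- vapply(dx_visit, function(v) max(visits[visits < v]), numeric(1))
    event_time[observed] <- onset_midpoint(dx_visit, prev)
  }
  data.frame(subject_id = truth$subject_id, event_time = event_time,
             event_observed = observed, true_event_time = true_t,
             censor_time = last_attended, baseline_hazard = lam0)
}

#' Generate a complete synthetic cohort
#'
#' End-to-end generator: subject-level disease trajectories and
#' demographics, theta (latent, or measured from generated phantom scans),
#' cognitive composites, and conversion outcomes, plus a ground-truth table
#' that pipeline stages never see.
#'
#' With `imaging = "latent"` the cohort's `theta` column is the latent map
#' `theta0 + theta_gain * severity` plus measurement noise — cheap, for
#' statistical stages. With `imaging = "phantom"` eigenvalue phantoms are
#' generated per subject-visit and returned (in memory, or written as
#' NIfTI under `out_dir` with a manifest); the `theta` column is left NA
#' for the imaging pipeline to fill.
#'
#' @param config a [synthetic_config()].
#' @param imaging `"latent"` (default) or `"phantom"`.
#' @param out_dir optional directory for NIfTI output in phantom mode.
#' @return list of class `"synthetic_cohort"`: `cohort` (long visit-level
#'   data frame), `subjects` (one row per subject), `truth`, and in phantom
#'   mode `scans` (named list of `eigenvalue_volume`, names
#'   `<subject>_t<visit>`) or `manifest` (data frame of paths).
#' @export
generate_cohort <- function(config, imaging = c("latent", "phantom"),
                            out_dir = NULL) {
  imaging <- match.arg(imaging)
  set.seed(config$rng_seed)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  s0 <- stats::rbeta(n, config$severity_shape1, config$severity_shape2)
  rate <- pmax(0, stats::rnorm(n, config$progression_mean,
                               config$progression_sd))
  t_img_max <- max(config$visit_times_imaging)
  truth <- data.frame(
    subject_id = ids, severity0 = s0, progression_rate = rate,
    theta_latent_baseline = config$theta0 + config$theta_gain * s0,
    dtheta_latent = config$theta_gain *
      (severity_at(s0, rate, t_img_max) - s0))
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  sex <- stats::rbinom(n, 1, config$male_fraction)
  iq <- stats::rnorm(n, config$iq_mean, config$iq_sd)
  cog <- simulate_cognition(config, truth)
  conv <- simulate_conversion(config, truth)
  truth$true_event_time <- conv$true_event_time
  truth <- cbind(truth, cog$slopes[, -1, drop = FALSE])

  cohort <- cog$visits
  cohort$theta <- NA_real_
  if (imaging == "latent") {
    img <- cohort$visit_time %in% config$visit_times_imaging
    sev <- severity_at(truth$severity0[match(cohort$subject_id, ids)],
                       truth$progression_rate[match(cohort$subject_id, ids)],
                       cohort$visit_time)
    cohort$theta[img] <- config$theta0 + config$theta_gain * sev[img] +
      stats::rnorm(sum(img), 0, config$theta_meas_sd)
  }
  subj <- data.frame(subject_id = ids, age_baseline = age, sex = sex,
                     premorbid_iq = iq)
  cohort <- merge(cohort, subj, by = "subject_id")
  cohort <- merge(cohort,
                  conv[, c("subject_id", "event_time", "event_observed")],
                  by = "subject_id")
  cohort$converted <- cohort$event_observed
  cohort <- cohort[order(cohort$subject_id, cohort$visit_time), ]
  rownames(cohort) <- NULL
  out <- list(cohort = cohort, subjects = merge(subj, conv, by = "subject_id"),
              truth = truth, config = config)
  if (imaging == "phantom") {
    scans <- list()
    manifest <- NULL
    for (i in seq_len(n)) {
      for (v in config$visit_times_imaging) {
        sev <- severity_at(s0[i], rate[i], v)
        seed_i <- (config$rng_seed * 131L + i * 7L + as.integer(v)) %% .Machine$integer.max
        vol <- make_phantom(config, sev, seed_i)
        key <- sprintf("%s_t%d", ids[i], as.integer(v))
        if (is.null(out_dir)) {
          scans[[key]] <- vol
        } else {
          path <- file.path(out_dir, paste0(key, "_eig.nii.gz"))
          write_volume(vol$lambdas, path, config$voxel_size)
          manifest <- rbind(manifest,
                            data.frame(subject_id = ids[i], visit_time = v,
                                       path = path))
        }
      }
    }
    if (is.null(out_dir)) out$scans <- scans else out$manifest <- manifest
  }
  class(out) <- "synthetic_cohort"
  out
}

#' Generate the healthy reference pool
#'
#' Phantoms (or latent spectra metadata) for a healthy aging sample with
#' severity near zero, used to pool the segmentation fit and to select the
#' reference spectrum.
#'
#' @param config a [synthetic_config()].
#' @return named list of `eigenvalue_volume` objects, names `H###_t0`.
#' @export
generate_healthy_scans <- function(config) {
  set.seed(config$rng_seed + 104729L)
  n <- config$n_healthy
  sev <- stats::runif(n, 0, 0.03)
  out <- list()
  for (i in seq_len(n)) {
    seed_i <- (config$rng_seed * 131L + 900000L + i) %% .Machine$integer.max
    out[[sprintf("H%03d_t0", i)]] <- make_phantom(config, sev[i], seed_i)
  }
  out
}
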