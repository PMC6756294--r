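# Shared fixtures, all built in code at test time.

# Unit gradient directions: 12 fixed non-collinear vectors (vertices of an
# icosahedron hemisphere plus fill-ins), adequate for a tensor fit.
fixture_bvecs <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(1, phi, 0), c(1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(1, 1, 1), c(1, 1, -1),
             c(1, -1, 1), c(-1, 1, 1), c(1, 0, 0), c(0, 1, 0))
  v / sqrt(rowSums(v^2))
}

# Noise-free DWI synthesized from one tensor applied to every in-mask voxel.
fixture_dwi <- function(D, dims = c(4, 4, 4), b = 1000, s0 = 1000,
                        n_b0 = 2, bvecs = fixture_bvecs()) {
  n_dir <- nrow(bvecs)
  bvals <- c(rep(0, n_b0), rep(b, n_dir))
  g <- rbind(matrix(0, n_b0, 3), bvecs)
  sig_per_vol <- vapply(seq_along(bvals), function(i) {
    s0 * exp(-bvals[i] * drop(t(g[i, ]) %*% D %*% g[i, ]))
  }, numeric(1))
  signal <- array(rep(sig_per_vol, each = prod(dims)),
                  c(dims, length(bvals)))
  dwi_volume(signal, bvals, g, array(TRUE, dims))
}

# Random rotation matrix (Haar-ish via QR, det +1).
fixture_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q * sign(diag(qr.R(qrd)))[col(Q)]
}

# pq_volume holding given (p, q) pairs (one voxel each) in a 1-D-ish grid.
fixture_pq <- function(p, q) {
  n <- length(p)
  dims <- c(n, 1, 1)
  pq_volume(array(p, dims), array(q, dims), array(TRUE, dims))
}

# Hand-built pq_histogram on an nb x nb grid over [0, 1]^2 with the given
# sparse counts (rows: i, j, count).
fixture_hist <- function(cells, nb = 8) {
  counts <- matrix(0L, nb, nb)
  counts[cbind(cells[, 1], cells[, 2])] <- as.integer(cells[, 3])
  structure(list(bin_edges_p = seq(0, 1, length.out = nb + 1),
                 bin_edges_q = seq(0, 1, length.out = nb + 1),
                 counts = counts, n_total = sum(counts), n_clipped = 0L),
            class = "pq_histogram")
}

# k-medians partition cost: count-weighted Euclidean distance to the
# coordinate-wise weighted median of each cluster. Shared cost definition
# for the exhaustive oracle and for evaluating a fitted partition.
oracle_partition_cost <- function(pts, a) {
  wmed <- function(x, w) {
    o <- order(x); cw <- cumsum(w[o]); x[o][which(cw >= sum(w) / 2)[1]]
  }
  cost <- 0
  for (c in unique(a)) {
    sel <- a == c
    cx <- wmed(pts[sel, 1], pts[sel, 3])
    cy <- wmed(pts[sel, 2], pts[sel, 3])
    cost <- cost + sum(pts[sel, 3] *
                         sqrt((pts[sel, 1] - cx)^2 + (pts[sel, 2] - cy)^2))
  }
  cost
}

# Exhaustive k-medians oracle: minimum partition cost over every assignment
# of points to k clusters. Independent of the package's alternating fit.
oracle_kmedians_cost <- function(pts, k) {
  n <- nrow(pts)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    best <- min(best, oracle_partition_cost(pts, a))
  }
  best
}

# Partition produced by a fitted model on the nonzero bins of a histogram.
fitted_partition <- function(hist, model) {
  pts <- dsegr:::hist_points(hist)
  d2 <- outer(pts[, 1], model$centroids[, 1], "-")^2 +
    outer(pts[, 2], model$centroids[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

# Random valid spectrum (percentages summing to 100).
fixture_spectrum <- function(id = "X", t = 0, k = 16, concentration = 1) {
  v <- stats::rgamma(k, concentration)
  dseg_spectrum(100 * v / sum(v), subject_id = id, visit_time = t)
}

# Baseline theta measured from phantom scans through the full imaging
# chain (phantoms -> pq -> pooled histogram -> k-medians -> spectra ->
# healthy reference -> theta). Returns one row per subject together with
# the generator truth and conversion outcomes. Shared by the synthetic
# tests and the end-to-end acceptance criterion.
measured_theta_baseline <- function(cfg, n_bins = c(96, 96)) {
  gen <- generate_cohort(cfg, imaging = "latent")
  healthy <- generate_healthy_scans(cfg)
  pq_h <- lapply(healthy, compute_pq)
  pq_p <- list()
  for (i in seq_len(cfg$n_subjects)) {
    seed_i <- (cfg$rng_seed * 131L + i * 7L) %% .Machine$integer.max
    vol <- make_phantom(cfg, gen$truth$severity0[i], seed_i)
    pq_p[[gen$truth$subject_id[i]]] <- compute_pq(vol)
  }
  h <- build_pq_histogram(c(pq_h, unname(pq_p)), n_bins = n_bins)
  model <- kmedians_fit(h, 16)
  spec_of <- function(pq, id) {
    compute_spectrum(assign_segments(pq, model), subject_id = id,
                     visit_time = 0)
  }
  ref <- select_reference(unname(mapply(spec_of, pq_h, names(pq_h),
                                        SIMPLIFY = FALSE)))
  th <- vapply(names(pq_p), function(id) {
    spectrum_angle(spec_of(pq_p[[id]], id), ref$reference_spectrum)
  }, numeric(1))
  out <- gen$subjects
  out$theta_hat <- th[out$subject_id]
  out$severity0 <- gen$truth$severity0[match(out$subject_id,
                                             gen$truth$subject_id)]
  out
}

# Balanced longitudinal cohort with known random-intercept/slope truth.
fixture_longitudinal <- function(n, times, slope_mean, slope_sd,
                                 int_mean = 2, int_sd = 0.5, noise_sd = 0.2) {
  ids <- sprintf("S%03d", seq_len(n))
  slopes <- stats::rnorm(n, slope_mean, slope_sd)
  ints <- stats::rnorm(n, int_mean, int_sd)
  d <- expand.grid(subject_id = ids, visit_time = times,
                   stringsAsFactors = FALSE)
  i <- match(d$subject_id, ids)
  d$y <- ints[i] + slopes[i] * d$visit_time +
    stats::rnorm(nrow(d), 0, noise_sd)
  list(data = d, slopes = stats::setNames(slopes, ids),
       intercepts = stats::setNames(ints, ids))
}
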