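#' Pooled two-dimensional (p,q) histogram
#'
#' Pools in-mask (p,q) values across scans into a 2-D count histogram. The
#' grid spans `[0, P99.9]` of each axis over the pooled data (robust to
#' extreme fitted voxels); values beyond the upper edge are clipped into the
#' end bin and counted in `n_clipped`. Segmentation is fitted to this
#' histogram — the empirical probability density of the pooled (p,q) cloud —
#' rather than to raw voxels, so the fit cost is independent of cohort size.
#'
#' @param pq_scans a `pq_volume` or list of `pq_volume` objects.
#' @param n_bins integer pair, bins per axis (default `c(256, 256)`).
#' @param upper optional pair of fixed upper edges (mm^2/s) overriding the
#'   quantile rule.
#' @return an object of class `"pq_histogram"`: `bin_edges_p`,
#'   `bin_edges_q`, `counts` (matrix p-bins x q-bins), `n_total`,
#'   `n_clipped`.
#' @export
build_pq_histogram <- function(pq_scans, n_bins = c(256L, 256L), upper = NULL) {
  if (inherits(pq_scans, "pq_volume")) pq_scans <- list(pq_scans)
  stopifnot(length(pq_scans) >= 1, all(n_bins >= 16))
  p <- unlist(lapply(pq_scans, function(s) s$p[s$mask]), use.names = FALSE)
  q <- unlist(lapply(pq_scans, function(s) s$q[s$mask]), use.names = FALSE)
  if (length(p) == 0) stop("no voxels pooled: all masks empty")
  if (is.null(upper)) {
    upper <- c(stats::quantile(p, 0.999, names = FALSE),
               stats::quantile(q, 0.999, names = FALSE))
  }
  upper[upper <= 0] <- max(upper, 1e-12)   # degenerate all-zero axis
  edges_p <- seq(0, upper[1], length.out = n_bins[1] + 1L)
  edges_q <- seq(0, upper[2], length.out = n_bins[2] + 1L)
  ip <- findInterval(p, edges_p, all.inside = TRUE)
  iq <- findInterval(q, edges_q, all.inside = TRUE)
  n_clipped <- sum(p > upper[1] | q > upper[2])
  counts <- matrix(0L, n_bins[1], n_bins[2])
  tab <- tabulate((iq - 1L) * n_bins[1] + ip, nbins = n_bins[1] * n_bins[2])
  counts[] <- tab
  structure(list(bin_edges_p = edges_p, bin_edges_q = edges_q,
                 counts = counts, n_total = length(p),
                 n_clipped = n_clipped),
            class = "pq_histogram")
}

# Lower weighted median of x with non-negative weights.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

# Nonzero bin centres and counts of a pq_histogram as a 3-column matrix.
hist_points <- function(hist) {
  cp <- (hist$bin_edges_p[-1] + hist$bin_edges_p[-length(hist$bin_edges_p)]) / 2
  cq <- (hist$bin_edges_q[-1] + hist$bin_edges_q[-length(hist$bin_edges_q)]) / 2
  nz <- which(hist$counts > 0, arr.ind = TRUE)
  cbind(p = cp[nz[, 1]], q = cq[nz[, 2]], w = hist$counts[hist$counts > 0])
}

# One run of alternating k-medians from a given centroid matrix.
# Assignment: Euclidean nearest centroid (ties to lowest index). Update:
# count-weighted coordinate-wise median, accepted only if it does not
# increase that cluster's weighted Euclidean cost (guarantees a monotone
# objective; the guard is almost never triggered). Empty clusters are
# reseeded at the point farthest from its current centroid.
kmedians_run <- function(pts, cen, tol, max_iter) {
  w <- pts[, 3]
  obj_trace <- numeric(0)
  n_reseeded <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- outer(pts[, 1], cen[, 1], "-")^2 + outer(pts[, 2], cen[, 2], "-")^2
    assign <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(pts)), assign)])
    empty <- setdiff(seq_len(nrow(cen)), unique(assign))
    if (length(empty)) {
      for (k in empty) {
        far <- which.max(dmin)
        cen[k, ] <- pts[far, 1:2]
        dmin[far] <- 0
        n_reseeded <- n_reseeded + 1L
      }
      next
    }
    obj_trace <- c(obj_trace, sum(w * dmin))
    new_cen <- cen
    for (k in seq_len(nrow(cen))) {
      sel <- assign == k
      cand <- c(weighted_median(pts[sel, 1], w[sel]),
                weighted_median(pts[sel, 2], w[sel]))
      old_cost <- sum(w[sel] * sqrt((pts[sel, 1] - cen[k, 1])^2 +
                                    (pts[sel, 2] - cen[k, 2])^2))
      new_cost <- sum(w[sel] * sqrt((pts[sel, 1] - cand[1])^2 +
                                    (pts[sel, 2] - cand[2])^2))
      if (new_cost <= old_cost) new_cen[k, ] <- cand
    }
    moved <- max(sqrt(rowSums((new_cen - cen)^2)))
    cen <- new_cen
    if (moved <= tol) break
  }
  d2 <- outer(pts[, 1], cen[, 1], "-")^2 + outer(pts[, 2], cen[, 2], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(pts)), assign)])
  list(centroids = cen, assign = assign, objective = sum(w * dmin),
       n_iterations = iter, obj_trace = c(obj_trace, sum(w * dmin)),
       n_reseeded = n_reseeded)
}

# Deterministic initial centroids: a grid of weighted marginal quantiles.
# For square k this is the sqrt(k) x sqrt(k) grid (4x4 for the default
# k = 16); otherwise paired marginal quantiles along the diagonal.
kmedians_init <- function(pts, k) {
  wq <- function(x, w, probs) {
    o <- order(x); x <- x[o]; cw <- cumsum(w[o]) / sum(w)
    vapply(probs, function(pr) x[which(cw >= pr)[1]], numeric(1))
  }
  r <- sqrt(k)
  if (abs(r - round(r)) < 1e-9) {
    r <- as.integer(round(r))
    probs <- (seq_len(r) - 0.5) / r
    qp <- wq(pts[, 1], pts[, 3], probs)
    qq <- wq(pts[, 2], pts[, 3], probs)
    cen <- as.matrix(expand.grid(p = qp, q = qq))
  } else {
    probs <- (seq_len(k) - 0.5) / k
    cen <- cbind(wq(pts[, 1], pts[, 3], probs), wq(pts[, 2], pts[, 3], probs))
  }
  # collapse exact duplicates by jittering deterministically along p
  dup <- duplicated(round(cen, 15))
  if (any(dup)) {
    span <- diff(range(pts[, 1])) + diff(range(pts[, 2]))
    cen[dup, 1] <- cen[dup, 1] + seq_len(sum(dup)) * 1e-9 * max(span, 1e-12)
  }
  unname(cen)
}

#' Fit the 16-segment k-medians model of (p,q) space
#'
#' Alternating k-medians on the count-weighted nonzero bin centres of the
#' pooled histogram: Euclidean nearest-centroid assignment (matching the
#' Voronoi partition of the segmented plane) and count-weighted
#' coordinate-wise median centroid updates. The objective — the
#' count-weighted sum of Euclidean distances to assigned centroids — is
#' non-increasing across iterations. Initialisation is deterministic (a grid
#' of weighted marginal quantiles), so the fit needs no RNG; for small
#' problems (at most 12 nonzero bins and k at most 4) every k-subset of bin
#' centres is tried as a start and the best run kept, which in practice
#' attains the global optimum.
#'
#' @param hist a [build_pq_histogram()] result.
#' @param k number of segments (default 16, the published segmentation).
#' @param tol convergence tolerance on maximum centroid displacement in
#'   mm^2/s (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return an object of class `"dseg_model"`: `centroids` (k x 2 matrix,
#'   fit order), `canonical_order` (permutation; see
#'   [canonical_segment_order()]), `objective`, `n_iterations`,
#'   `obj_trace`, `n_reseeded`, `seed_policy`.
#' @export
kmedians_fit <- function(hist, k = 16L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(hist, "pq_histogram"))
  pts <- hist_points(hist)
  if (nrow(pts) < k) {
    stop("degenerate histogram: ", nrow(pts), " nonzero bins < k = ", k)
  }
  if (nrow(pts) <= 12 && k <= 4) {
    subsets <- utils::combn(nrow(pts), k)
    best <- NULL
    for (j in seq_len(ncol(subsets))) {
      run <- kmedians_run(pts, pts[subsets[, j], 1:2, drop = FALSE],
                          tol, max_iter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
    seed_policy <- "exhaustive-subset-starts"
  } else {
    best <- kmedians_run(pts, kmedians_init(pts, k), tol, max_iter)
    seed_policy <- "deterministic-quantile-grid"
  }
  model <- structure(
    list(centroids = best$centroids, canonical_order = seq_len(k),
         objective = best$objective, n_iterations = best$n_iterations,
         obj_trace = best$obj_trace, n_reseeded = best$n_reseeded,
         k = as.integer(k), seed_policy = seed_policy),
    class = "dseg_model")
  model$canonical_order <- canonical_segment_order(model)
  model
}

#' Canonical segment ordering
#'
#' Orders segments for spectrum axes along the microstructural gradient:
#' ascending centroid isotropy `p`, ties broken by descending anisotropy
#' `q`. The permutation maps canonical rank to fit-order centroid index and
#' is stored in the model so spectra are comparable across runs.
#'
#' @param model a [kmedians_fit()] model.
#' @return integer permutation of `1:k`; `canonical_order[r]` is the
#'   fit-order index of the r-th canonical segment.
#' @export
canonical_segment_order <- function(model) {
  stopifnot(inherits(model, "dseg_model"))
  order(model$centroids[, 1], -model$centroids[, 2])
}

#' Assign every in-mask voxel to its segment
#'
#' Labels each in-mask voxel with the canonical index of the
#' Euclidean-nearest centroid (the Voronoi cell containing its (p,q)
#' value); ties go to the lowest canonical index. Voxels outside the mask
#' are labelled 0.
#'
#' @param pq a `pq_volume`.
#' @param model a fitted [kmedians_fit()] model.
#' @return an object of class `"segment_labels"`: `labels` (3-D integer
#'   array), `mask`, `k`, `model_id` (the model's objective and k, a cheap
#'   fingerprint).
#' @export
assign_segments <- function(pq, model) {
  stopifnot(inherits(pq, "pq_volume"), inherits(model, "dseg_model"))
  cen <- model$centroids[model$canonical_order, , drop = FALSE]
  idx <- which(pq$mask)
  pv <- pq$p[idx]; qv <- pq$q[idx]
  d2 <- outer(pv, cen[, 1], "-")^2 + outer(qv, cen[, 2], "-")^2
  lab <- max.col(-d2, ties.method = "first")   # lowest canonical index on ties
  labels <- array(0L, dim(pq$mask))
  labels[idx] <- lab
  structure(list(labels = labels, mask = pq$mask, k = model$k,
                 model_id = sprintf("k%d-obj%.6g", model$k, model$objective)),
            class = "segment_labels")
}

#' Serialize / deserialize a dseg_model as JSON
#'
#' @param model a `dseg_model`.
#' @param path output path.
#' @return `path` (write) or a `dseg_model` (read).
#' @export
write_dseg_model <- function(model, path) {
  jsonlite::write_json(
    list(centroids = model$centroids, canonical_order = model$canonical_order,
         objective = model$objective, n_iterations = model$n_iterations,
         k = model$k, seed_policy = model$seed_policy),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dseg_model
#' @export
read_dseg_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centroids = matrix(x$centroids, ncol = 2),
                 canonical_order = as.integer(x$canonical_order),
                 objective = x$objective, n_iterations = x$n_iterations,
                 obj_trace = numeric(0), n_reseeded = NA_integer_,
                 k = as.integer(x$k), seed_policy = x$seed_policy),
            class = "dseg_model")
}
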