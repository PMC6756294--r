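test_that("histogram conserves pooled voxel counts", {
  one <- fixture_pq(rep(2e-3, 50), rep(5e-4, 50))
  h1 <- build_pq_histogram(one, n_bins = c(16, 16))
  expect_identical(sum(h1$counts > 0), 1L)
  expect_identical(max(h1$counts), 50L)
  expect_identical(h1$n_total, 50L)

  set.seed(3)
  two <- list(fixture_pq(stats::runif(100, 0, 3e-3), stats::runif(100, 0, 1e-3)),
              fixture_pq(stats::runif(100, 0, 3e-3), stats::runif(100, 0, 1e-3)))
  h2 <- build_pq_histogram(two, n_bins = c(32, 32))
  expect_identical(h2$n_total, 200L)
  expect_identical(sum(h2$counts), 200L)

  empty <- pq_volume(array(0, c(2, 2, 2)), array(0, c(2, 2, 2)),
                     array(FALSE, c(2, 2, 2)))
  expect_error(build_pq_histogram(empty), "no voxels pooled")
})

test_that("uniform (p,q) bins match the multinomial expectation", {
  set.seed(11)
  n <- 64000
  pqv <- fixture_pq(stats::runif(n, 0, 1e-3), stats::runif(n, 0, 1e-3))
  nb <- 16
  h <- build_pq_histogram(pqv, n_bins = c(nb, nb), upper = c(1e-3, 1e-3))
  p_cell <- 1 / nb^2
  expected <- n * p_cell
  sigma <- sqrt(n * p_cell * (1 - p_cell))
  expect_true(all(abs(h$counts - expected) < 4 * sigma))
})

test_that("k-medians handles point masses and matches the brute-force oracle", {
  h1 <- fixture_hist(cbind(3, 5, 40))
  m1 <- kmedians_fit(h1, k = 1)
  pts <- dsegr:::hist_points(h1)
  expect_equal(unname(m1$centroids[1, ]), unname(pts[1, 1:2]))
  expect_equal(m1$objective, 0)

  set.seed(21)
  for (rep in 1:5) {             # 6 weighted points, k = 2, oracle search
    cells <- cbind(sample(8, 6), sample(8, 6), sample(1:9, 6, replace = TRUE))
    cells <- cells[!duplicated(cells[, 1:2]), , drop = FALSE]
    h <- fixture_hist(cells)
    m <- kmedians_fit(h, k = 2)
    pts <- dsegr:::hist_points(h)
    expect_equal(oracle_partition_cost(pts, fitted_partition(h, m)),
                 oracle_kmedians_cost(pts, 2),
                 tolerance = 1e-12)
  }
})

test_that("the 4-tissue cohort yields 16 populated segments", {
  cfg <- synthetic_config(n_subjects = 8, n_healthy = 3, rng_seed = 5)
  gen <- generate_cohort(cfg, imaging = "phantom")
  pqs <- lapply(gen$scans, compute_pq)
  h <- build_pq_histogram(pqs, n_bins = c(128, 128))
  m <- kmedians_fit(h, k = 16)
  labs <- lapply(pqs, assign_segments, model = m)
  pooled <- table(factor(unlist(lapply(labs, function(l) l$labels[l$mask])),
                         levels = 1:16))
  expect_identical(nrow(m$centroids), 16L)
  expect_true(all(pooled > 0))
})

test_that("objective is monotone non-increasing on random histograms", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    pqv <- fixture_pq(stats::rgamma(n, 2, 1000), stats::rgamma(n, 2, 2000))
    h <- build_pq_histogram(pqv, n_bins = c(24, 24))
    m <- kmedians_fit(h, k = 4)
    expect_true(all(diff(m$obj_trace) <= 1e-12 * max(1, m$obj_trace[1])))
  }
})

test_that("assignment matches an exhaustive nearest-centroid scan", {
  set.seed(41)
  cfg <- synthetic_config(rng_seed = 5)
  vol <- make_phantom(cfg, 0.4, 99)
  pq <- compute_pq(vol)
  h <- build_pq_histogram(pq, n_bins = c(64, 64))
  m <- kmedians_fit(h, k = 16)
  seg <- assign_segments(pq, m)
  cen <- m$centroids[m$canonical_order, ]
  idx <- which(pq$mask)
  pick <- sample(idx, 200)
  for (v in pick) {
    d <- sqrt((pq$p[v] - cen[, 1])^2 + (pq$q[v] - cen[, 2])^2)
    expect_identical(seg$labels[v], which.min(d))
  }
  # voxel exactly at a centroid gets that centroid's segment
  at <- fixture_pq(cen[7, 1], cen[7, 2])
  expect_identical(assign_segments(at, m)$labels[1], 7L)
})

test_that("equidistant voxels break ties toward the lowest canonical index", {
  m <- structure(list(centroids = rbind(c(1e-3, 5e-4), c(3e-3, 5e-4)),
                      canonical_order = 1:2, objective = 0,
                      n_iterations = 1L, obj_trace = 0, n_reseeded = 0L,
                      k = 2L, seed_policy = "manual"),
                 class = "dseg_model")
  mid <- fixture_pq(2e-3, 5e-4)          # equidistant to both centroids
  expect_identical(assign_segments(mid, m)$labels[1], 1L)
})

test_that("canonical order sorts by p ascending, q descending, idempotently", {
  cen <- rbind(c(2, 1), c(1, 1), c(1, 3), c(3, 0))
  m <- structure(list(centroids = cen, canonical_order = 1:4, objective = 0,
                      n_iterations = 1L, obj_trace = 0, n_reseeded = 0L,
                      k = 4L, seed_policy = "manual"),
                 class = "dseg_model")
  ord <- canonical_segment_order(m)
  expect_identical(ord, c(3L, 2L, 1L, 4L))   # p=1,q=3 first; equal p: hi q
  sorted <- structure(m, class = "dseg_model")
  sorted$centroids <- cen[ord, ]
  expect_identical(canonical_segment_order(sorted), 1:4)
})

test_that("fit, assignment and serialization are deterministic", {
  cfg <- synthetic_config(rng_seed = 13)
  pq <- compute_pq(make_phantom(cfg, 0.5, 7))
  h <- build_pq_histogram(pq, n_bins = c(64, 64))
  m1 <- kmedians_fit(h)
  m2 <- kmedians_fit(h)
  expect_identical(m1$centroids, m2$centroids)
  s1 <- assign_segments(pq, m1)
  s2 <- assign_segments(pq, m2)
  expect_identical(s1$labels, s2$labels)
  path <- tempfile(fileext = ".json")
  write_dseg_model(m1, path)
  m3 <- read_dseg_model(path)
  expect_equal(m3$centroids, m1$centroids, tolerance = 1e-12)
  expect_identical(m3$canonical_order, m1$canonical_order)
  expect_error(kmedians_fit(fixture_hist(cbind(1:3, 1:3, 1)), k = 16),
               "degenerate histogram")
})
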