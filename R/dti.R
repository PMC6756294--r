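#' Diffusion-weighted image volume
#'
#' Container for a 4-D diffusion-weighted acquisition: the signal array, the
#' per-volume b-values and unit gradient directions, a cerebrum mask, and the
#' voxel size. The mask is taken as the cerebrum mask; eddy-current and
#' motion correction and cerebellum removal are assumed done upstream.
#'
#' @param signal 4-D numeric array `(x, y, z, volume)`, non-negative.
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs matrix `n_volumes x 3` of gradient directions; rows with
#'   `b > 0` must have unit norm (tolerance 1e-6).
#' @param mask 3-D logical array matching the spatial grid.
#' @param voxel_size mm triplet.
#' @return an object of class `"dwi_volume"`.
#' @export
dwi_volume <- function(signal, bvals, bvecs, mask, voxel_size = c(2.5, 2.5, 2.5)) {
  stopifnot(length(dim(signal)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(signal)[1:3] == dim(mask))) stop("mask grid mismatch")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != dim(signal)[4] || length(bvals) != dim(signal)[4]) {
    stop("bvals/bvecs must have one entry per volume")
  }
  if (!any(bvals == 0)) stop("at least one b=0 volume is required")
  nz <- bvals > 0
  norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("bvecs for b>0 volumes must be unit vectors")
  }
  if (any(signal < 0)) stop("signal must be non-negative")
  structure(list(signal = signal, bvals = as.numeric(bvals), bvecs = bvecs,
                 mask = array(as.logical(mask), dim(mask)),
                 voxel_size = voxel_size),
            class = "dwi_volume")
}

#' Eigenvalue volume
#'
#' Per-voxel sorted diffusion tensor eigenvalues (`lambda1 >= lambda2 >=
#' lambda3`, mm^2/s) with mask and voxel size. `n_clamped` records how many
#' in-mask voxels had negative fitted eigenvalues clamped to zero.
#'
#' @param lambdas 4-D array `(x, y, z, 3)`.
#' @param mask 3-D logical array.
#' @param voxel_size mm triplet.
#' @param n_clamped integer provenance count (default 0).
#' @return an object of class `"eigenvalue_volume"`.
#' @export
eigenvalue_volume <- function(lambdas, mask, voxel_size = c(2.5, 2.5, 2.5),
                              n_clamped = 0L) {
  stopifnot(length(dim(lambdas)) == 4L, dim(lambdas)[4] == 3L)
  if (!all(dim(lambdas)[1:3] == dim(mask))) stop("mask grid mismatch")
  lam <- matrix(lambdas, ncol = 3)
  inm <- as.vector(mask)
  if (any(!is.finite(lam[inm, ]))) stop("non-finite eigenvalues inside mask")
  if (any(lam[inm, 1] < lam[inm, 2] - 1e-12) ||
      any(lam[inm, 2] < lam[inm, 3] - 1e-12)) {
    stop("eigenvalues must be sorted descending within the mask")
  }
  structure(list(lambdas = lambdas,
                 mask = array(as.logical(mask), dim(mask)),
                 voxel_size = voxel_size, n_clamped = as.integer(n_clamped)),
            class = "eigenvalue_volume")
}

# Analytic eigenvalues of many symmetric 3x3 tensors (rows of a 6-column
# matrix dxx,dyy,dzz,dxy,dxz,dyz), returned sorted descending. Uses the
# trigonometric solution of the characteristic cubic.
sym3_eigenvalues <- function(d6) {
  dxx <- d6[, 1]; dyy <- d6[, 2]; dzz <- d6[, 3]
  dxy <- d6[, 4]; dxz <- d6[, 5]; dyz <- d6[, 6]
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 +
    2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (dxx - q) / p; b22 <- (dyy - q) / p; b33 <- (dzz - q) / p
    b12 <- dxy / p; b13 <- dxz / p; b23 <- dyz / p
    # det(B)/2 where B = (D - q I)/p
    detb <- b11 * (b22 * b33 - b23^2) -
      b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Ordinary least squares on the log-signal per voxel, sharing one design
#' matrix across voxels. Negative fitted eigenvalues are clamped to zero and
#' counted; voxels with non-positive signal are dropped from the mask and
#' counted.
#'
#' @param dwi a [dwi_volume()].
#' @return an [eigenvalue_volume()]; attributes `n_excluded` (voxels dropped
#'   for non-positive signal) and the clamping count `n_clamped` record the
#'   policy applied.
#' @export
fit_tensor_loglinear <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nz <- dwi$bvals > 0
  dirs <- unique(round(dwi$bvecs[nz, , drop = FALSE], 10))
  # antipodal directions are collinear for tensor estimation
  canon <- t(apply(dirs, 1, function(g) if (g[max(which(g != 0), 1)] < 0) -g else g))
  n_dir <- nrow(unique(round(canon, 10)))
  if (n_dir < 6) {
    stop("insufficient directions: ", n_dir, " usable (need >= 6)")
  }
  X <- cbind(
    1,
    -dwi$bvals * dwi$bvecs[, 1]^2,
    -dwi$bvals * dwi$bvecs[, 2]^2,
    -dwi$bvals * dwi$bvecs[, 3]^2,
    -2 * dwi$bvals * dwi$bvecs[, 1] * dwi$bvecs[, 2],
    -2 * dwi$bvals * dwi$bvecs[, 1] * dwi$bvecs[, 3],
    -2 * dwi$bvals * dwi$bvecs[, 2] * dwi$bvecs[, 3]
  )
  dims <- dim(dwi$mask)
  idx <- which(as.vector(dwi$mask))
  sig <- matrix(dwi$signal, ncol = dim(dwi$signal)[4])[idx, , drop = FALSE]
  bad <- rowSums(sig <= 0) > 0
  n_excluded <- sum(bad)
  mask <- dwi$mask
  mask[idx[bad]] <- FALSE
  idx <- idx[!bad]
  lam_arr <- array(0, c(dims, 3))
  n_clamped <- 0L
  if (length(idx)) {
    logs <- t(log(sig[!bad, , drop = FALSE]))           # volumes x voxels
    beta <- qr.coef(qr(X), logs)                         # 7 x voxels
    d6 <- t(beta[2:7, , drop = FALSE])                   # dxx dyy dzz dxy dxz dyz
    lam <- sym3_eigenvalues(d6)
    n_clamped <- sum(rowSums(lam < 0) > 0)
    lam[lam < 0] <- 0
    for (j in 1:3) {
      slice <- array(0, dims)
      slice[idx] <- lam[, j]
      lam_arr[, , , j] <- slice
    }
  }
  out <- eigenvalue_volume(lam_arr, mask, dwi$voxel_size, n_clamped)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Compute isotropic (p) and anisotropic (q) diffusion maps
#'
#' For sorted eigenvalues with mean diffusivity `MD = (l1 + l2 + l3)/3`,
#' the isotropy magnitude is `p = sqrt(3) * MD` and the anisotropy magnitude
#' is the deviatoric norm `q = sqrt((l1-MD)^2 + (l2-MD)^2 + (l3-MD)^2)`,
#' both in mm^2/s. This function is the single place to swap in an
#' alternative (p,q) normalisation convention.
#'
#' @param eig an [eigenvalue_volume()].
#' @return an object of class `"pq_volume"`: list with 3-D arrays `p` and
#'   `q` (zero outside the mask), `mask` and `voxel_size`.
#' @export
compute_pq <- function(eig) {
  stopifnot(inherits(eig, "eigenvalue_volume"))
  dims <- dim(eig$mask)
  lam <- matrix(eig$lambdas, ncol = 3)
  md <- rowMeans(lam)
  p <- sqrt(3) * md
  q <- sqrt((lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2)
  inm <- as.vector(eig$mask)
  p[!inm] <- 0; q[!inm] <- 0
  structure(list(p = array(p, dims), q = array(q, dims),
                 mask = eig$mask, voxel_size = eig$voxel_size),
            class = "pq_volume")
}

#' Construct a pq_volume from raw maps
#'
#' @param p,q 3-D numeric arrays in mm^2/s.
#' @param mask 3-D logical array.
#' @param voxel_size mm triplet.
#' @return an object of class `"pq_volume"`.
#' @export
pq_volume <- function(p, q, mask, voxel_size = c(2.5, 2.5, 2.5)) {
  stopifnot(all(dim(p) == dim(mask)), all(dim(q) == dim(mask)))
  inm <- as.vector(mask)
  if (any(p[inm] < 0) || any(q[inm] < 0)) stop("p and q must be >= 0 in mask")
  p[!mask] <- 0; q[!mask] <- 0
  structure(list(p = p, q = q, mask = array(as.logical(mask), dim(mask)),
                 voxel_size = voxel_size),
            class = "pq_volume")
}
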