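# Nuclei detection: Gaussian smoothing -> local-maxima seeds above an
# intensity percentile -> intensity-weighted EM refinement of a 3D
# Gaussian mixture with one component per seed. Deterministic by design:
# means start at the seeds, no random restarts.

# separable 3D Gaussian filter, sigma per axis in voxels; reflective border
gaussian_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  # move target axis first, pad reflectively, convolve as a matrix
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  # reflected index for positions (1-r):(n+r), clamped for tiny arrays
  pos <- (1 - r):(n + r)
  refl <- ifelse(pos < 1, 2 - pos, ifelse(pos > n, 2 * n - pos, pos))
  refl <- pmin(n, pmax(1L, refl))
  mp <- m[refl, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * mp[j:(j + n - 1L), , drop = FALSE]
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

# strict 26-neighbourhood local maxima; returns voxel index matrix (z,y,x)
local_maxima3 <- function(arr) {
  d <- dim(arr)
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- seq_len(d[1]) + dz; sy <- seq_len(d[2]) + dy; sx <- seq_len(d[3]) + dx
    okz <- sz >= 1 & sz <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okx <- sx >= 1 & sx <= d[3]
    nb <- array(-Inf, d)
    nb[okz, oky, okx] <- arr[sz[okz], sy[oky], sx[okx]]
    is_max <- is_max & (arr > nb)
  }
  which(is_max, arr.ind = TRUE)
}

# voxel index (1-based z,y,x rows) -> physical um coordinates (x,y,z cols)
voxel_to_um <- function(idx, spacing) {
  idx <- matrix(idx, ncol = 3)
  # 0-based voxel indexing: voxel i sits at i * spacing
  cbind(x = (idx[, 3] - 1) * spacing[3],
        y = (idx[, 2] - 1) * spacing[2],
        z = (idx[, 1] - 1) * spacing[1])
}

#' Detect cell nuclei in a red-channel volume
#'
#' Seeds are the strict 26-neighbourhood local maxima of the
#' Gaussian-smoothed volume that exceed the given intensity percentile of
#' the smoothed voxel distribution. A 3D Gaussian mixture with one
#' component per seed is then refined by EM on the above-threshold
#' voxels, each weighted by its raw intensity, giving sub-voxel centroids
#' and per-cell covariances in physical units. The fit is deterministic:
#' means start at the seeds, covariances isotropic at one voxel, no
#' random restarts, a fixed iteration cap and relative log-likelihood
#' tolerance.
#'
#' @param volume a red-channel [worm_volume()].
#' @param smoothing_sigma Gaussian sigma in voxels per (z, y, x) axis;
#'   default 1 voxel each, suppressing single-voxel noise maxima.
#' @param intensity_percentile seed/support threshold as a percentile of
#'   smoothed intensities, in (0, 100); default 99.
#' @param max_components optional cap on the number of seeds (brightest
#'   kept first).
#' @param em_max_iter,em_tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A list of `detected_cell` objects with fields `centroid`
#'   (x, y, z um), `peak` (raw intensity), `mask` (voxel index matrix,
#'   z,y,x rows), `mean`, `cov` (3x3, um^2), `weight`.
#' @export
detect_cells <- function(volume, smoothing_sigma = c(1, 1, 1),
                         intensity_percentile = 99, max_components = Inf,
                         em_max_iter = 100L, em_tol = 1e-6) {
  stopifnot(inherits(volume, "worm_volume"))
  if (intensity_percentile <= 0 || intensity_percentile >= 100)
    stop("intensity_percentile must be in (0, 100)", call. = FALSE)
  sm <- gaussian_smooth3(volume$data, smoothing_sigma)
  thr <- stats::quantile(sm, intensity_percentile / 100, names = FALSE)
  seeds <- local_maxima3(sm)
  if (nrow(seeds) > 0) seeds <- seeds[sm[seeds] > thr, , drop = FALSE]
  if (nrow(seeds) == 0L) {
    stage_log("detect_cells: 0 seeds above percentile %.2f",
              intensity_percentile)
    return(list())
  }
  if (nrow(seeds) > max_components) {
    o <- order(sm[seeds], decreasing = TRUE)
    seeds <- seeds[o[seq_len(max_components)], , drop = FALSE]
  }
  vox <- which(sm > thr, arr.ind = TRUE)
  X <- voxel_to_um(vox, volume$spacing)
  w <- volume$data[vox]            # raw intensities weight the fit
  mu0 <- voxel_to_um(seeds, volume$spacing)
  fit <- gmm_em_weighted(X, w, mu0, volume$spacing,
                         max_iter = em_max_iter, tol = em_tol)
  # hard-assign above-threshold voxels to components for masks
  cells <- vector("list", length(fit$keep))
  for (ci in seq_along(fit$keep)) {
    k <- fit$keep[ci]
    mk <- vox[fit$assign == k, , drop = FALSE]
    cells[[ci]] <- structure(list(
      centroid = fit$mu[k, ],
      peak = if (nrow(mk)) max(volume$data[mk]) else NA_real_,
      mask = mk,
      mean = fit$mu[k, ],
      cov = fit$sigma[[k]],
      weight = fit$pi[k]), class = "detected_cell")
  }
  cells <- Filter(function(cc) nrow(cc$mask) > 0, cells)
  stage_log("detect_cells: %d seeds -> %d cells", nrow(seeds), length(cells))
  cells
}

# intensity-weighted EM for a Gaussian mixture with fixed component count
gmm_em_weighted <- function(X, w, mu0, spacing, max_iter = 100L,
                            tol = 1e-6) {
  K <- nrow(mu0); n <- nrow(X)
  mu <- mu0
  # isotropic-ish init at one voxel per axis (um^2), floor for stability
  s0 <- diag(pmax(spacing[c(3, 2, 1)], 0.2)^2)
  sigma <- rep(list(s0), K)
  pik <- rep(1 / K, K)
  W <- sum(w)
  ll_old <- -Inf
  logdens <- matrix(0, n, K)
  ridge <- diag(1e-6, 3)
  for (it in seq_len(max_iter)) {
    for (k in 1:K) {
      ch <- tryCatch(chol(sigma[[k]]), error = function(e) NULL)
      if (is.null(ch)) { ch <- chol(sigma[[k]] + diag(1e-3, 3)) }
      xc <- sweep(X, 2, mu[k, ])
      q <- backsolve(ch, t(xc), transpose = TRUE)
      logdens[, k] <- log(pik[k]) - sum(log(diag(ch))) -
        0.5 * colSums(q^2) - 1.5 * log(2 * pi)
    }
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(w * lse) / W
    resp <- exp(logdens - lse)
    for (k in 1:K) {
      rw <- resp[, k] * w
      sk <- sum(rw)
      if (sk <= 1e-12) next   # starved component keeps its parameters
      mu[k, ] <- colSums(X * rw) / sk
      xc <- sweep(X, 2, mu[k, ])
      sigma[[k]] <- crossprod(xc * sqrt(rw)) / sk + ridge
      pik[k] <- sk / W
    }
    pik <- pik / sum(pik)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  # drop components whose covariance is not positive-definite
  keep <- integer(0)
  for (k in 1:K) {
    ev <- eigen(sigma[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0) keep <- c(keep, k)
    else warning("dropping mixture component ", k,
                 " with non-positive-definite covariance")
  }
  assign <- keep[apply(logdens[, keep, drop = FALSE], 1, which.max)]
  list(mu = mu, sigma = sigma, pi = pik, keep = keep, assign = assign)
}

#' Segment autofluorescence landmarks from the green channel
#'
#' Returns the centroids of local intensity maxima whose smoothed value
#' exceeds the given percentile of all smoothed voxel intensities. The
#' default percentile (99.85) suits gut-granule autofluorescence under
#' typical confocal settings and can be tuned for other imaging
#' conditions.
#'
#' @param green_volume a green-channel [worm_volume()].
#' @param percentile_threshold percentile in (0, 100]; 100 yields an
#'   empty cloud (nothing exceeds the global maximum strictly).
#' @param smoothing_sigma Gaussian sigma in voxels per (z, y, x) axis.
#' @return A [point_cloud()] in the image frame (um).
#' @export
segment_landmarks <- function(green_volume, percentile_threshold = 99.85,
                              smoothing_sigma = c(1, 1, 1)) {
  stopifnot(inherits(green_volume, "worm_volume"))
  if (percentile_threshold <= 0 || percentile_threshold > 100)
    stop("percentile_threshold must be in (0, 100]", call. = FALSE)
  sm <- gaussian_smooth3(green_volume$data, smoothing_sigma)
  thr <- stats::quantile(sm, percentile_threshold / 100, names = FALSE)
  mx <- local_maxima3(sm)
  if (nrow(mx) > 0) mx <- mx[sm[mx] > thr, , drop = FALSE]
  stage_log("segment_landmarks: %d landmarks above percentile %.2f",
            nrow(mx), percentile_threshold)
  point_cloud(voxel_to_um(mx, green_volume$spacing),
              intensity = if (nrow(mx)) green_volume$data[mx],
              frame = "image")
}

#' Collect detected-cell centroids into a point cloud
#'
#' @param cells list of `detected_cell` from [detect_cells()].
#' @return A [point_cloud()] in the image frame.
#' @export
cells_to_cloud <- function(cells) {
  if (length(cells) == 0L)
    return(point_cloud(matrix(0, 0, 3), frame = "image"))
  point_cloud(do.call(rbind, lapply(cells, `[[`, "centroid")),
              intensity = vapply(cells, `[[`, 0, "peak"),
              frame = "image")
}
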