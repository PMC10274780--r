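#' Construct a worm body-axes frame
#'
#' A right-handed orthonormal frame (AP, LR, DV) anchored at the centroid
#' of the cell cloud. The constructor re-orthonormalizes its inputs
#' (Gram-Schmidt) and enforces dv = ap x lr, then checks the frame
#' invariants to 1e-9.
#'
#' @param origin 3-vector, frame origin in um (image frame).
#' @param ap,lr,dv unit 3-vectors; `dv` defaults to `ap x lr`.
#' @return An object of class `body_axes`.
#' @export
body_axes <- function(origin, ap, lr, dv = NULL) {
  origin <- as.numeric(origin); ap <- as.numeric(ap); lr <- as.numeric(lr)
  stopifnot(length(origin) == 3L, length(ap) == 3L, length(lr) == 3L)
  ap <- ap / sqrt(sum(ap^2))
  lr <- lr - sum(lr * ap) * ap
  nl <- sqrt(sum(lr^2))
  if (nl < 1e-12) stop("lr is parallel to ap", call. = FALSE)
  lr <- lr / nl
  dv <- cross3(ap, lr)
  ax <- structure(list(origin = origin, ap = ap, lr = lr, dv = dv,
                       rotation_deg = NULL, symmetry_score = NULL),
                  class = "body_axes")
  check_axes(ax)
  ax
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_axes <- function(ax, tol = 1e-9) {
  v <- rbind(ax$ap, ax$lr, ax$dv)
  if (any(abs(sqrt(rowSums(v^2)) - 1) >= tol))
    stop("axes not unit length", call. = FALSE)
  if (abs(sum(ax$ap * ax$lr)) >= tol || abs(sum(ax$ap * ax$dv)) >= tol ||
      abs(sum(ax$lr * ax$dv)) >= tol)
    stop("axes not orthogonal", call. = FALSE)
  if (any(abs(cross3(ax$ap, ax$lr) - ax$dv) >= tol))
    stop("frame not right-handed (ap x lr != dv)", call. = FALSE)
  invisible(ax)
}

#' @export
print.body_axes <- function(x, ...) {
  cat("<body_axes>\n")
  for (nm in c("ap", "lr", "dv"))
    cat(sprintf("  %s: (% .4f, % .4f, % .4f)\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) um\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Initial body axes by principal component analysis
#'
#' The AP, LR and DV axes are taken as the 1st, 2nd and 3rd principal
#' directions of the centered point cloud: the worm head is elongated
#' along AP and wider along LR than DV, so with enough points the
#' principal directions align with the anatomical axes. Signs are
#' adjusted to a right-handed frame; the polarity of each axis (which end
#' is anterior, etc.) is not determined here — flip with [flip_axes()] or
#' take it from ground truth / user input.
#'
#' @param points n x 3 matrix of positions in um (or a [point_cloud()]).
#' @return A [body_axes()] with origin at the cloud centroid.
#' @export
pca_axes <- function(points) {
  pts <- cloud_points(points)
  if (nrow(pts) < 3L)
    stop("need >= 3 points for axes estimation", call. = FALSE)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  s <- svd(x, nu = 0)
  # rank must be >= 2: a collinear cloud has no defined LR direction
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("degenerate (collinear) point cloud", call. = FALSE)
  body_axes(origin = ctr, ap = s$v[, 1], lr = s$v[, 2])
}

cloud_points <- function(x) {
  if (inherits(x, "point_cloud")) x$points
  else as.matrix(x)
}

#' Correct the AP axis using autofluorescence landmarks
#'
#' Multi-cell strains often express in a compact or lopsided subset of
#' head neurons, so PCA on the cells alone can tilt the AP estimate.
#' Autofluorescent gut/body granules (green channel) span the full body
#' length; pooling them with the cells before PCA anchors the first
#' principal direction to the true head axis. The origin remains the
#' centroid of the *cell* cloud so worm-frame coordinates stay comparable
#' across animals.
#'
#' @param cell_cloud cells, n x 3 um matrix or [point_cloud()].
#' @param landmark_cloud autofluorescence landmark positions, same frame.
#' @return A [body_axes()].
#' @export
correct_ap_axis <- function(cell_cloud, landmark_cloud) {
  cells <- cloud_points(cell_cloud)
  lms <- if (is.null(landmark_cloud)) matrix(0, 0, 3)
         else cloud_points(landmark_cloud)
  if (nrow(lms) == 0L) {
    warning("empty landmark cloud; falling back to PCA on cells alone")
    return(pca_axes(cells))
  }
  ax <- pca_axes(rbind(cells, lms))
  ax$origin <- colMeans(cells)
  ax
}

#' Deviation from bilateral symmetry about a candidate plane
#'
#' Reflects every point across the plane through the cloud centroid with
#' the given normal and measures the distance from each reflection to its
#' nearest neighbour among the original points. Perfectly mirrored pairs
#' contribute 0. The score is the mean of the `k_lowest` smallest
#' distances, so it keys on the best-mirrored cells (the bilateral neuron
#' pairs) and tolerates unpaired midline cells and dropout.
#'
#' @param points n x 3 um matrix or [point_cloud()].
#' @param plane_normal unit 3-vector, the candidate LR direction.
#' @param k_lowest number of smallest reflection distances to average;
#'   default 7, the expected minimum number of bilateral pairs.
#' @return Non-negative symmetry-deviation score (um).
#' @export
symmetry_deviation <- function(points, plane_normal, k_lowest = 7L) {
  pts <- cloud_points(points)
  n <- nrow(pts)
  if (k_lowest < 1L || k_lowest > n)
    stop("k_lowest must be in [1, number of points]", call. = FALSE)
  nrm <- as.numeric(plane_normal)
  nrm <- nrm / sqrt(sum(nrm^2))
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr) %*% nrm            # signed distance to plane
  refl <- pts - 2 * d %*% t(nrm)
  # squared distances reflections (rows) vs originals (cols)
  g <- tcrossprod(refl, pts)
  sq <- outer(rowSums(refl^2), rowSums(pts^2), "+") - 2 * g
  sq[sq < 0] <- 0
  # exclude a point's own pre-image only when the reflection coincides
  # with it (point on the plane): distance < 1e-12
  diag(sq)[sqrt(diag(sq)) < 1e-12] <- Inf
  nn <- sqrt(apply(sq, 1, min))
  mean(sort(nn)[seq_len(k_lowest)])
}

#' Correct the LR (and DV) axes by bilateral-symmetry search
#'
#' Head neurons are largely bilaterally symmetric, so the true LR axis is
#' the normal of the cloud's best mirror plane. Candidate normals are the
#' initial LR rotated about the AP axis by every angle on a grid
#' (default +/-20 deg in 1 deg steps), which keeps every candidate
#' orthogonal to AP. The frame whose normal minimizes
#' [symmetry_deviation()] wins; ties break toward the smallest absolute
#' angle, then the negative one. DV is recomputed as ap x lr.
#'
#' @param points cell positions, n x 3 um matrix or [point_cloud()].
#' @param initial_axes a [body_axes()], typically from [correct_ap_axis()].
#' @param max_angle_deg,step_deg search half-range and increment, degrees.
#' @param k_lowest passed to [symmetry_deviation()].
#' @return A [body_axes()] with `rotation_deg` (selected angle) and
#'   `symmetry_score` (its deviation score) filled in.
#' @export
correct_lr_axis <- function(points, initial_axes, max_angle_deg = 20,
                            step_deg = 1, k_lowest = 7L) {
  check_axes(initial_axes)
  if (step_deg <= 0 || max_angle_deg < 0 || (max_angle_deg > 0 && step_deg > max_angle_deg))
    stop("need 0 < step_deg <= max_angle_deg", call. = FALSE)
  pts <- cloud_points(points)
  angles <- if (max_angle_deg == 0) 0 else
    sort(unique(c(seq(-max_angle_deg, max_angle_deg, by = step_deg), 0)))
  # tie-break priority: |angle| ascending, negative before positive
  angles <- angles[order(abs(angles), angles)]
  best <- NULL
  for (a in angles) {
    lr_a <- rotate_about(initial_axes$lr, initial_axes$ap, a * pi / 180)
    sc <- symmetry_deviation(pts, lr_a, k_lowest)
    if (is.null(best) || sc < best$score - 1e-15)
      best <- list(angle = a, lr = lr_a, score = sc)
  }
  out <- body_axes(initial_axes$origin, initial_axes$ap, best$lr)
  out$rotation_deg <- best$angle
  out$symmetry_score <- best$score
  out
}

# Rodrigues rotation of v about unit axis u by theta radians
rotate_about <- function(v, u, theta) {
  u <- u / sqrt(sum(u^2))
  v * cos(theta) + cross3(u, v) * sin(theta) +
    u * sum(u * v) * (1 - cos(theta))
}

#' Flip axis polarity
#'
#' The PCA/symmetry pipeline fixes the axes only up to sign; anatomical
#' polarity (anterior end, left side, dorsal side) comes from the user or
#' from ground truth. Because the frame must stay right-handed
#' (dv = ap x lr), only an even number of sign flips is realizable; a
#' lone `dv` flip is applied by negating DV and LR together.
#'
#' @param axes a [body_axes()].
#' @param ap,lr,dv logical; flip the sign of that axis.
#' @return A [body_axes()].
#' @export
flip_axes <- function(axes, ap = FALSE, lr = FALSE, dv = FALSE) {
  # flipping lr (or ap) negates ap x lr, so dv tracks xor(ap, lr)
  # automatically; a dv request of the opposite parity toggles lr, whose
  # side assignment the symmetry search leaves ambiguous anyway
  if (dv != xor(ap, lr)) lr <- !lr
  a <- axes$ap * if (ap) -1 else 1
  l <- axes$lr * if (lr) -1 else 1
  out <- body_axes(axes$origin, a, l)
  out$rotation_deg <- axes$rotation_deg
  out$symmetry_score <- axes$symmetry_score
  out
}

#' Sign-agnostic angular deviation between two frames
#'
#' Per axis, the angle `acos(|a . b|)` in degrees, in [0, 90]; the sign
#' ambiguity of PCA axes is thus ignored.
#'
#' @param axes_a,axes_b [body_axes()] frames.
#' @return Named numeric vector `(ap, lr, dv)` in degrees.
#' @export
axes_angle_deviation <- function(axes_a, axes_b) {
  ang <- function(u, v) {
    d <- min(1, abs(sum(u * v)))
    acos(d) * 180 / pi
  }
  c(ap = ang(axes_a$ap, axes_b$ap),
    lr = ang(axes_a$lr, axes_b$lr),
    dv = ang(axes_a$dv, axes_b$dv))
}

#' Full axes-prediction pipeline for one worm
#'
#' PCA initialization on cells, AP correction with landmarks, then the
#' bilateral-symmetry LR/DV correction.
#'
#' @inheritParams correct_lr_axis
#' @param cell_cloud cells in the image frame.
#' @param landmark_cloud autofluorescence landmarks (may be `NULL`).
#' @return A [body_axes()].
#' @export
predict_axes <- function(cell_cloud, landmark_cloud = NULL,
                         max_angle_deg = 20, step_deg = 1, k_lowest = 7L) {
  ax <- if (is.null(landmark_cloud) ||
            nrow(cloud_points(landmark_cloud)) == 0L)
    pca_axes(cell_cloud)
  else correct_ap_axis(cell_cloud, landmark_cloud)
  correct_lr_axis(cell_cloud, ax, max_angle_deg = max_angle_deg,
                  step_deg = step_deg, k_lowest = k_lowest)
}
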