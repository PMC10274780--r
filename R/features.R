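#' Express a point cloud in the worm body-axes frame
#'
#' Each image-frame point p maps to
#' ((p - origin) . ap, (p - origin) . lr, (p - origin) . dv), so the
#' returned columns read (AP, LR, DV) in um. Idempotence is guarded: a
#' cloud already tagged `"worm"` is refused.
#'
#' @param cloud a [point_cloud()] in the image frame.
#' @param axes a [body_axes()].
#' @return A [point_cloud()] with `frame = "worm"`.
#' @export
to_worm_frame <- function(cloud, axes) {
  stopifnot(inherits(cloud, "point_cloud"))
  check_axes(axes)
  if (cloud$frame == "worm")
    stop("cloud is already in the worm frame", call. = FALSE)
  R <- rbind(axes$ap, axes$lr, axes$dv)
  xc <- sweep(cloud$points, 2, axes$origin)
  point_cloud(xc %*% t(R), intensity = cloud$intensity,
              cell = cloud$cell, frame = "worm")
}

#' Pairwise positional features of a worm-frame cloud
#'
#' For every ordered cell pair (i, j):
#' * `pa[i, j]`, `lr[i, j]`, `dv[i, j]` — TRUE iff cell i precedes cell j
#'   along the +AP / +LR / +DV direction (i.e. has the strictly smaller
#'   coordinate). Antisymmetric with a FALSE diagonal.
#' * `ang[i, j, ]` — the unit displacement vector from cell i to cell j
#'   in worm-frame components.
#'
#' Exact coordinate ties (|difference| < 1e-12 um) are broken by cell
#' order and flagged in the log; coincident cells get an NA angular
#' entry (flagged in `degenerate`).
#'
#' @param worm_cloud a [point_cloud()] with `frame = "worm"`, >= 2 cells.
#' @return An object of class `pairwise_features` with fields `pa`, `lr`,
#'   `dv` (logical matrices), `ang` (n x n x 3 array), `cell` (ids),
#'   `degenerate` (2-column matrix of coincident pairs).
#' @export
extract_features <- function(worm_cloud) {
  stopifnot(inherits(worm_cloud, "point_cloud"))
  if (worm_cloud$frame != "worm")
    stop("features are defined on worm-frame clouds; run to_worm_frame()",
         call. = FALSE)
  P <- worm_cloud$points
  n <- nrow(P)
  if (n < 2L) stop("need >= 2 cells for pairwise features", call. = FALSE)
  tol <- 1e-12
  rel <- function(coord) {
    d <- outer(coord, coord, "-")        # d[i,j] = coord_i - coord_j
    tie <- abs(d) < tol & upper.tri(d)
    if (any(tie))
      stage_log("extract_features: %d coordinate tie(s) broken by cell order",
                sum(tie))
    m <- d < -tol                         # i strictly precedes j
    m[abs(d) < tol] <- FALSE
    # tie-break by cell id order: earlier cell precedes
    m[tie] <- TRUE
    diag(m) <- FALSE
    m
  }
  pa <- rel(P[, 1]); lr <- rel(P[, 2]); dv <- rel(P[, 3])
  ang <- array(NA_real_, dim = c(n, n, 3))
  D <- array(0, dim = c(n, n, 3))
  for (k in 1:3) D[, , k] <- outer(P[, k], P[, k], function(a, b) b - a)
  nrm <- sqrt(D[, , 1]^2 + D[, , 2]^2 + D[, , 3]^2)
  degenerate <- which(nrm < tol & upper.tri(nrm), arr.ind = TRUE)
  nz <- nrm >= tol
  for (k in 1:3) {
    a <- ang[, , k]
    a[nz] <- D[, , k][nz] / nrm[nz]
    ang[, , k] <- a
  }
  if (nrow(degenerate))
    stage_log("extract_features: %d coincident cell pair(s); angular entries NA",
              nrow(degenerate))
  structure(list(pa = pa, lr = lr, dv = dv, ang = ang,
                 cell = worm_cloud$cell, degenerate = degenerate),
            class = "pairwise_features")
}
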