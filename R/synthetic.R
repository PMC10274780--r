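# Synthetic worms with known ground truth. The generator emulates the
# statistical structure the pipeline assumes: a reference map of labelled
# neurons in an elongated ellipsoidal head with exactly mirrored
# bilateral pairs, per-worm positional jitter, expression dropout
# (transgene mosaicism), rigid rotation with bounded off-plane tilt,
# autofluorescence landmarks strung along the body, rendered two-channel
# volumes, and annotator label noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth reference map
#'
#' Canonical worm-frame positions (AP, LR, DV in um) for `n_total`
#' labelled neurons inside an ellipsoidal head, of which `n_pairs`
#' left/right pairs are exact mirror images across the LR = 0 plane and
#' the rest sit on the midline (LR = 0). Defaults mirror a multi-cell
#' reporter strain: 37 neurons with 15 bilateral pairs in a head about
#' 100 um long and wider (30 um) than deep (20 um), so typical
#' positional jitter of ~1 um stays small against inter-neuron
#' distances, as in real volumes.
#'
#' @param n_total number of labels (>= 2).
#' @param n_pairs number of bilateral pairs (2 * n_pairs <= n_total).
#' @param seed integer seed; the map is a deterministic function of it.
#' @param semi_axes ellipsoid semi-axes (AP, LR, DV) in um.
#' @param ap_range,dv_range sampling sub-ranges as fractions of the
#'   semi-axis, for emulating spatially biased expression patterns.
#' @param min_separation rejection-sampling minimum distance between
#'   neurons (um).
#' @return An object of class `reference_map`: `labels`, `positions`
#'   (worm frame), `pairs` (left/right label matrix), `semi_axes`.
#' @export
make_reference_map <- function(n_total = 37L, n_pairs = 15L, seed = 1L,
                               semi_axes = c(50, 15, 10),
                               ap_range = c(-1, 1), dv_range = c(-1, 1),
                               min_separation = 3) {
  if (n_total < 2L) stop("need n_total >= 2", call. = FALSE)
  if (2L * n_pairs > n_total)
    stop("2 * n_pairs must be <= n_total", call. = FALSE)
  n_unpaired <- n_total - 2L * n_pairs
  with_seed(seed, {
    placed <- matrix(0, 0, 3)
    draw <- function(lr_min) {
      for (try in 1:2000) {
        p <- c(stats::runif(1, ap_range[1], ap_range[2]),
               stats::runif(1, if (lr_min > 0) lr_min / semi_axes[2] else 0,
                            if (lr_min > 0) 1 else 0),
               stats::runif(1, dv_range[1], dv_range[2])) * semi_axes
        if (lr_min == 0) p[2] <- 0
        if (sum((p / semi_axes)^2) > 1) next
        cand <- if (lr_min > 0) rbind(p, p * c(1, -1, 1)) else rbind(p)
        if (nrow(placed) == 0 ||
            min(as.matrix(stats::dist(rbind(placed, cand)))[
              seq_len(nrow(placed)), nrow(placed) + seq_len(nrow(cand)),
              drop = FALSE]) >= min_separation)
          return(p)
      }
      stop("could not place neurons with the requested separation",
           call. = FALSE)
    }
    labels <- character(0); pos <- matrix(0, 0, 3)
    pairs <- matrix(character(0), 0, 2)
    for (k in seq_len(n_pairs)) {
      p <- draw(lr_min = min_separation / 2)
      lab <- sprintf("N%02d", k)
      labels <- c(labels, paste0(lab, "L"), paste0(lab, "R"))
      # +LR side is the left side under the package convention
      pos <- rbind(pos, p, p * c(1, -1, 1))
      pairs <- rbind(pairs, c(paste0(lab, "L"), paste0(lab, "R")))
      placed <- rbind(placed, p, p * c(1, -1, 1))
    }
    for (k in seq_len(n_unpaired)) {
      p <- draw(lr_min = 0)
      labels <- c(labels, sprintf("U%02d", k))
      pos <- rbind(pos, p)
      placed <- rbind(placed, p)
    }
    dimnames(pos) <- list(labels, c("ap", "lr", "dv"))
    structure(list(labels = labels, positions = pos, pairs = pairs,
                   semi_axes = semi_axes),
              class = "reference_map")
  })
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("<reference_map> %d neurons (%d bilateral pairs), head %s um\n",
              length(x$labels), nrow(x$pairs),
              paste(2 * x$semi_axes, collapse = " x ")))
  invisible(x)
}

#' Synthetic-worm sampling configuration
#'
#' Defaults describe a realistic multi-cell imaging condition:
#' positional jitter 1 um, 20% mosaic dropout, off-plane tilt up to
#' 20 degrees, 40 autofluorescence landmarks, 10% annotator error.
#'
#' @param jitter_sigma isotropic positional jitter sd (um).
#' @param dropout per-cell probability of transgene loss.
#' @param max_tilt_deg maximum off-plane tilt of the sampled rigid
#'   rotation (degrees); in-plane orientation is uniform.
#' @param n_landmarks autofluorescence points along the body envelope.
#' @param landmark_extent landmark AP span as a multiple of the head
#'   semi-axis (landmarks extend beyond the neurons, into the body).
#' @param landmark_radial_sd radial scatter of landmarks about the body
#'   axis (um), matching the width of the autofluorescent gut.
#' @param annotator_error per-cell label-corruption probability.
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(jitter_sigma = 1, dropout = 0.2,
                             max_tilt_deg = 20, n_landmarks = 40L,
                             landmark_extent = 1.4, landmark_radial_sd = 2,
                             annotator_error = 0.1, seed = 1L) {
  stopifnot(jitter_sigma >= 0, dropout >= 0, dropout <= 1,
            max_tilt_deg >= 0, annotator_error >= 0, annotator_error < 0.5)
  structure(list(jitter_sigma = jitter_sigma, dropout = dropout,
                 max_tilt_deg = max_tilt_deg, n_landmarks = n_landmarks,
                 landmark_extent = landmark_extent,
                 landmark_radial_sd = landmark_radial_sd,
                 annotator_error = annotator_error, seed = seed),
            class = "synthetic_config")
}

random_rotation <- function(max_tilt_deg) {
  # in-plane spin (about DV) uniform; off-plane tilt about a random
  # in-plane axis, uniform up to the bound
  spin <- stats::runif(1, 0, 2 * pi)
  tilt <- stats::runif(1, 0, max_tilt_deg) * pi / 180
  tilt_axis_ang <- stats::runif(1, 0, 2 * pi)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  u <- c(cos(tilt_axis_ang), sin(tilt_axis_ang), 0)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  Rt <- diag(3) + sin(tilt) * K + (1 - cos(tilt)) * K %*% K
  Rt %*% Rz(spin)
}

#' Sample one synthetic worm
#'
#' Applies mosaic dropout, positional jitter, and a rigid rotation +
#' translation to the reference map; draws autofluorescence landmarks
#' along the body envelope and transforms them with the same pose. The
#' true pose, true worm-frame positions and true labels are returned for
#' evaluation.
#'
#' @param ref a [make_reference_map()] result.
#' @param config a [synthetic_config()]; `config$seed` drives the draw.
#' @param worm_id identifier stamped on the annotation.
#' @return List of class `synthetic_worm`: `cloud` (image-frame
#'   [point_cloud()] of retained cells), `landmarks` (image-frame
#'   [point_cloud()]), `axes` (true [body_axes()]), `annotation` (true
#'   [annotation_set()]), `worm_cloud` (true worm-frame positions of the
#'   retained cells), `kept` (labels retained after dropout).
#' @export
sample_worm <- function(ref, config, worm_id = "sim") {
  stopifnot(inherits(ref, "reference_map"),
            inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- length(ref$labels)
    kept <- which(stats::runif(n) >= config$dropout)
    if (length(kept) < 3L) kept <- which(stats::runif(n) >= config$dropout)
    if (length(kept) < 3L)
      stop("dropout removed nearly all cells twice in a row", call. = FALSE)
    Pw <- ref$positions[kept, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(kept), 0, config$jitter_sigma),
             ncol = 3)
    R <- random_rotation(config$max_tilt_deg)
    t0 <- stats::runif(3, 60, 120)
    Pi <- Pw %*% t(R)
    Pi <- sweep(Pi, 2, t0, "+")
    lm_ap <- stats::runif(config$n_landmarks,
                          -config$landmark_extent * ref$semi_axes[1],
                          config$landmark_extent * ref$semi_axes[1])
    Lw <- cbind(lm_ap,
                stats::rnorm(config$n_landmarks, 0, config$landmark_radial_sd),
                stats::rnorm(config$n_landmarks, 0, config$landmark_radial_sd))
    Li <- sweep(Lw %*% t(R), 2, t0, "+")
    ctr_w <- colMeans(Pw)
    axes <- body_axes(origin = as.numeric(R %*% ctr_w + t0),
                      ap = R[, 1], lr = R[, 2])
    structure(list(
      cloud = point_cloud(Pi, cell = seq_along(kept), frame = "image"),
      landmarks = point_cloud(Li, frame = "image"),
      axes = axes,
      annotation = annotation_set(worm_id, "truth", seq_along(kept),
                                  ref$labels[kept]),
      worm_cloud = point_cloud(sweep(Pw, 2, ctr_w),
                               cell = seq_along(kept), frame = "worm"),
      kept = ref$labels[kept]),
      class = "synthetic_worm")
  })
}

#' Render a point set as a blobby fluorescence volume
#'
#' Sum of isotropic Gaussian intensity blobs at the given positions plus
#' a constant background, sampled on an anisotropic voxel grid, with
#' optional Poisson shot noise. Points outside the field of view are
#' clipped with a warning.
#'
#' @param points n x 3 um positions (x, y, z) or a [point_cloud()].
#' @param spacing voxel spacing (z, y, x) um.
#' @param psf_sigma blob sigma in um.
#' @param peak peak intensity per blob; `background` added everywhere.
#' @param dims optional (z, y, x) voxel counts; default fits the points
#'   with a 3 um margin.
#' @param origin um position of voxel (1,1,1); default from the fit.
#'   Detected centroids are reported relative to the volume grid, i.e.
#'   at `point - origin`.
#' @param channel channel tag for the returned volume.
#' @param poisson add Poisson noise (seeded).
#' @param seed RNG seed used when `poisson = TRUE`.
#' @return A [worm_volume()].
#' @export
render_volume <- function(points, spacing = c(0.3, 0.4, 0.4),
                          psf_sigma = 1, peak = 1000, background = 10,
                          dims = NULL, origin = NULL,
                          channel = c("red", "green"), poisson = FALSE,
                          seed = 1L) {
  channel <- match.arg(channel)
  pts <- cloud_points(points)
  if (is.null(origin))
    origin <- apply(pts, 2, min) - 3          # um, (x, y, z)
  if (is.null(dims)) {
    span <- apply(pts, 2, max) + 3 - origin   # (x, y, z) um
    dims <- ceiling(span[c(3, 2, 1)] / spacing) + 1
  }
  arr <- array(background, dim = dims)
  ax_z <- origin[3] + (seq_len(dims[1]) - 1) * spacing[1]
  ax_y <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  ax_x <- origin[1] + (seq_len(dims[3]) - 1) * spacing[3]
  clipped <- 0
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    if (p[1] < ax_x[1] || p[1] > ax_x[dims[3]] ||
        p[2] < ax_y[1] || p[2] > ax_y[dims[2]] ||
        p[3] < ax_z[1] || p[3] > ax_z[dims[1]]) {
      clipped <- clipped + 1
      next
    }
    wz <- which(abs(ax_z - p[3]) <= 4 * psf_sigma)
    wy <- which(abs(ax_y - p[2]) <= 4 * psf_sigma)
    wx <- which(abs(ax_x - p[1]) <= 4 * psf_sigma)
    gz <- exp(-(ax_z[wz] - p[3])^2 / (2 * psf_sigma^2))
    gy <- exp(-(ax_y[wy] - p[2])^2 / (2 * psf_sigma^2))
    gx <- exp(-(ax_x[wx] - p[1])^2 / (2 * psf_sigma^2))
    arr[wz, wy, wx] <- arr[wz, wy, wx] +
      peak * (gz %o% gy %o% gx)
  }
  if (clipped > 0)
    warning(clipped, " point(s) outside the rendered field were clipped")
  if (poisson)
    arr <- with_seed(seed, array(stats::rpois(length(arr), arr), dim = dims))
  worm_volume(arr, spacing, channel)
}

#' Corrupt a true annotation into several noisy annotator copies
#'
#' Each annotator independently mislabels each cell with probability
#' `error_rate`, replacing the true label with a uniformly drawn
#' candidate not currently assigned to another cell of that copy (so
#' each copy stays duplicate-free, as human annotators do); if every
#' candidate is in use, the cell exchanges labels with a random other
#' cell instead.
#'
#' @param truth a true [annotation_set()].
#' @param candidates a [candidate_list()] or character vector; the
#'   replacement-label universe.
#' @param error_rate per-cell corruption probability in [0, 0.5).
#' @param seed integer seed.
#' @param n_annotators number of copies (default 3).
#' @return List of [annotation_set()] objects.
#' @export
corrupt_annotations <- function(truth, candidates, error_rate, seed = 1L,
                                n_annotators = 3L) {
  stopifnot(inherits(truth, "annotation_set"),
            error_rate >= 0, error_rate < 0.5)
  labels_all <- if (inherits(candidates, "candidate_list"))
    candidates$labels else as.character(candidates)
  with_seed(seed, {
    lapply(seq_len(n_annotators), function(a) {
      labs <- truth$labels
      wrong <- which(stats::runif(length(labs)) < error_rate)
      for (i in wrong) {
        pool <- setdiff(labels_all, labs[-i])
        pool <- setdiff(pool, labs[i])
        if (length(pool)) {
          labs[i] <- pool[sample.int(length(pool), 1)]
        } else {
          j <- sample(setdiff(seq_along(labs), i), 1)
          tmp <- labs[i]; labs[i] <- labs[j]; labs[j] <- tmp
        }
      }
      annotation_set(truth$worm, paste0("annotator", a), truth$cells, labs)
    })
  })
}

align_axes_to_truth <- function(axes, truth) {
  flip_axes(axes,
            ap = sum(axes$ap * truth$ap) < 0,
            lr = sum(axes$lr * truth$lr) < 0,
            dv = sum(axes$dv * truth$dv) < 0)
}

#' Simulate a cohort of annotated worms
#'
#' Draws `n_worms` independent worms from one reference map, corrupts
#' the true labels into three annotator copies, and expresses each cloud
#' in the worm frame — either the true frame or the frame recovered by
#' the axes pipeline (PCA + landmark AP correction + symmetry LR
#' correction, polarity aligned to truth).
#'
#' @param ref a [make_reference_map()] result.
#' @param config a [synthetic_config()]; per-worm seeds are derived from
#'   `config$seed`.
#' @param n_worms cohort size.
#' @param use_true_axes use the generator's pose (TRUE) or run the axes
#'   recovery pipeline (FALSE).
#' @return List of worms in the layout [build_atlas()] and [loocv()]
#'   consume: each has `cloud` (worm frame), `annotations` (3 sets),
#'   `id`, plus `worm` (the full `synthetic_worm`) and `axes_used`.
#' @export
simulate_cohort <- function(ref, config, n_worms, use_true_axes = TRUE) {
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, n_worms))
  lapply(seq_len(n_worms), function(wi) {
    cfg <- config
    cfg$seed <- seeds[wi]
    sw <- sample_worm(ref, cfg, worm_id = paste0("worm", wi))
    axes <- if (use_true_axes) sw$axes else
      align_axes_to_truth(
        predict_axes(sw$cloud, sw$landmarks), sw$axes)
    cloud <- to_worm_frame(sw$cloud, axes)
    anns <- corrupt_annotations(sw$annotation, ref$labels,
                                cfg$annotator_error, seed = seeds[wi])
    list(cloud = cloud, annotations = anns, id = paste0("worm", wi),
         worm = sw, axes_used = axes)
  })
}
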