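# shared fixtures built in code; all randomness under fixed seeds

# rotation matrix about a unit axis (Rodrigues)
rot_mat <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# exactly mirror-symmetric cloud: n_pairs mirrored about the x = mx plane
mirror_cloud <- function(n_pairs, seed = 1, mx = 0) {
  set.seed(seed)
  right <- cbind(x = runif(n_pairs, 0.5, 3), y = runif(n_pairs, -5, 5),
                 z = runif(n_pairs, -2, 2))
  left <- right; left[, 1] <- -left[, 1]
  pts <- rbind(right, left)
  pts[, 1] <- pts[, 1] + mx
  pts
}

# five well-separated blob centers (um, world coords relative to origin 0)
blob_centers <- function() {
  cbind(c(4, 12, 20, 8, 16), c(4, 6, 4, 14, 14), c(3, 7, 4, 6, 3))
}

# tiny annotated cohort for atlas/crf/evaluation tests
tiny_cohort <- function(n_labels = 10, n_pairs = 4, n_worms = 4, sigma = 0,
                        dropout = 0, error = 0, seed = 7,
                        use_true_axes = TRUE) {
  ref <- make_reference_map(n_labels, n_pairs, seed = seed)
  cfg <- synthetic_config(jitter_sigma = sigma, dropout = dropout,
                          annotator_error = error, seed = seed + 1)
  list(ref = ref,
       worms = suppressMessages(suppressWarnings(
         simulate_cohort(ref, cfg, n_worms,
                         use_true_axes = use_true_axes))))
}

expect_valid_axes <- function(ax) {
  expect_s3_class(ax, "body_axes")
  v <- rbind(ax$ap, ax$lr, ax$dv)
  expect_true(all(abs(sqrt(rowSums(v^2)) - 1) < 1e-9))
  expect_lt(abs(sum(ax$ap * ax$lr)), 1e-9)
  expect_lt(abs(sum(ax$ap * ax$dv)), 1e-9)
  expect_lt(abs(sum(ax$lr * ax$dv)), 1e-9)
  expect_true(all(abs(wormid:::cross3(ax$ap, ax$lr) - ax$dv) < 1e-9))
}
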