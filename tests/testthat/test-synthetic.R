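test_that("reference maps have the requested structure and determinism", {
  ref <- make_reference_map(37, 15, seed = 3)
  expect_length(ref$labels, 37)
  expect_identical(nrow(ref$pairs), 15L)
  expect_identical(anyDuplicated(ref$labels), 0L)
  # mirrored pairs: positions equal under LR flip
  for (r in seq_len(nrow(ref$pairs))) {
    pl <- ref$positions[ref$pairs[r, 1], ]
    pr <- ref$positions[ref$pairs[r, 2], ]
    expect_equal(unname(pl * c(1, -1, 1)), unname(pr))
  }
  # unpaired neurons on the midline
  unpaired <- setdiff(ref$labels, c(ref$pairs))
  expect_true(all(ref$positions[unpaired, "lr"] == 0))
  # inside the stated ellipsoid
  expect_true(all(rowSums(sweep(ref$positions, 2, ref$semi_axes, "/")^2)
                  <= 1 + 1e-12))
  expect_identical(make_reference_map(37, 15, seed = 3), ref)
  expect_false(identical(make_reference_map(37, 15, seed = 4), ref))
  ref0 <- make_reference_map(6, 0, seed = 5)
  expect_identical(nrow(ref0$pairs), 0L)
  expect_error(make_reference_map(1, 0), "n_total")
  expect_error(make_reference_map(4, 3), "n_pairs")
})

test_that("noise-free identity-pose worms reproduce the reference exactly", {
  ref <- make_reference_map(12, 5, seed = 6)
  cfg <- synthetic_config(jitter_sigma = 0, dropout = 0, max_tilt_deg = 0,
                          annotator_error = 0, seed = 7)
  sw <- sample_worm(ref, cfg)
  # pose is a pure in-plane spin + translation; undo it via the true axes
  wf <- to_worm_frame(sw$cloud, sw$axes)
  expect_equal(unname(wf$points),
               unname(sweep(ref$positions, 2, colMeans(ref$positions))),
               tolerance = 1e-9)
  expect_identical(sw$annotation$labels, ref$labels)
  expect_equal(axes_angle_deviation(sw$axes, sw$axes), c(ap = 0, lr = 0,
                                                         dv = 0))
  expect_identical(sample_worm(ref, cfg)$cloud$points, sw$cloud$points)
})

test_that("dropout retains the binomially expected fraction of cells", {
  ref <- make_reference_map(20, 8, seed = 8)
  kept <- sapply(1:400, function(s) {
    cfg <- synthetic_config(jitter_sigma = 0, dropout = 0.3,
                            annotator_error = 0, seed = s)
    length(sample_worm(ref, cfg)$kept)
  })
  expect_lt(abs(mean(kept) / 20 - 0.7), 0.05)
})

test_that("sampled tilt stays within the configured bound", {
  ref <- make_reference_map(10, 4, seed = 9)
  for (s in 1:20) {
    cfg <- synthetic_config(jitter_sigma = 0, dropout = 0,
                            max_tilt_deg = 20, annotator_error = 0,
                            seed = s)
    sw <- sample_worm(ref, cfg)
    # off-plane tilt = angle between true AP and the imaging plane
    expect_lte(abs(sw$axes$ap[3]), sin(20 * pi / 180) + 1e-9)
  }
})

test_that("landmarks span the body envelope beyond the neurons", {
  ref <- make_reference_map(10, 4, seed = 10)
  cfg <- synthetic_config(jitter_sigma = 0, dropout = 0, max_tilt_deg = 0,
                          annotator_error = 0, seed = 11)
  sw <- sample_worm(ref, cfg)
  lm_w <- to_worm_frame(sw$landmarks, sw$axes)
  span <- diff(range(lm_w$points[, 1]))
  expect_gt(span, 2 * ref$semi_axes[1])            # longer than the head
  expect_lt(max(abs(lm_w$points[, 2])), 10)        # near the body axis
})

test_that("corrupted annotations are reproducible with the stated error rate", {
  ref <- make_reference_map(30, 12, seed = 12)
  truth <- annotation_set("w", "truth", seq_along(ref$labels), ref$labels)
  a1 <- corrupt_annotations(truth, ref$labels, error_rate = 0, seed = 13)
  expect_length(a1, 3)
  for (a in a1) expect_identical(a$labels, truth$labels)
  a2 <- corrupt_annotations(truth, ref$labels, error_rate = 0.2, seed = 14)
  expect_identical(corrupt_annotations(truth, ref$labels, 0.2, seed = 14),
                   a2)
  for (a in a2) expect_identical(anyDuplicated(a$labels), 0L)
  flips <- mean(sapply(a2, function(a) mean(a$labels != truth$labels)))
  expect_lt(abs(flips - 0.2), 0.15)
})

test_that("rendered volumes close the loop with detection", {
  ref <- make_reference_map(5, 2, seed = 15, semi_axes = c(9, 4, 3),
                            min_separation = 4)
  pos <- sweep(ref$positions, 2, apply(ref$positions, 2, min)) + 4
  vol <- render_volume(pos, spacing = c(0.3, 0.4, 0.4), psf_sigma = 1,
                       peak = 1000, background = 10, origin = c(0, 0, 0),
                       dims = c(40, 40, 80))
  cells <- suppressMessages(detect_cells(vol, intensity_percentile = 99.5))
  expect_length(cells, 5)
  cent <- do.call(rbind, lapply(cells, `[[`, "centroid"))
  for (i in 1:5)
    expect_lt(min(sqrt(colSums((t(cent) - pos[i, ])^2))), 0.4)
  # no contrast, no detections
  flat <- render_volume(pos, spacing = c(0.3, 0.4, 0.4), psf_sigma = 1,
                        peak = 0, background = 10, origin = c(0, 0, 0),
                        dims = c(40, 40, 80))
  expect_length(suppressMessages(
    detect_cells(flat, intensity_percentile = 99.5)), 0)
  # out-of-field points are clipped with a warning
  expect_warning(render_volume(rbind(c(200, 0, 0)),
                               spacing = c(0.3, 0.4, 0.4),
                               origin = c(0, 0, 0),
                               dims = c(10, 10, 10)), "clipped")
})

test_that("cohorts are deterministic and structurally complete", {
  coh <- tiny_cohort(n_labels = 8, n_pairs = 3, n_worms = 3, sigma = 0.5,
                     dropout = 0.2, error = 0.1, seed = 16)
  coh2 <- tiny_cohort(n_labels = 8, n_pairs = 3, n_worms = 3, sigma = 0.5,
                      dropout = 0.2, error = 0.1, seed = 16)
  expect_equal(coh$worms[[2]]$cloud$points, coh2$worms[[2]]$cloud$points)
  for (w in coh$worms) {
    expect_length(w$annotations, 3)
    expect_identical(w$cloud$frame, "worm")
    expect_identical(length(w$annotations[[1]]$cells),
                     nrow(w$cloud$points))
  }
})
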