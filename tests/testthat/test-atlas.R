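# hand-built two-cell worms for exactly computable atlas statistics
worm_from <- function(pos, labels, worm = "w", annotator = "a") {
  list(cloud = point_cloud(pos, cell = seq_len(nrow(pos)), frame = "worm"),
       annotations = list(annotation_set(worm, annotator,
                                         seq_len(nrow(pos)), labels)))
}

test_that("unanimous and split observations give the expected probabilities", {
  w1 <- worm_from(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "B"), "w1")
  w2 <- worm_from(rbind(c(0, 1, 2), c(1, -1, 1)), c("A", "B"), "w2")
  atl <- suppressMessages(build_atlas(list(w1, w2), c("A", "B", "C")))
  expect_identical(atl$counts["A", "B"], 2)
  expect_identical(atl$p_pa["A", "B"], 1)
  expect_identical(atl$p_pa["B", "A"], 0)
  # LR: w1 ties (0 vs 0) -> 0.5 each; w2 has A left of ... lr 1 > -1
  expect_equal(atl$p_lr["A", "B"], (0.5 + 0) / 2)
  # C never co-observed: defaults
  expect_identical(atl$counts["A", "C"], 0)
  expect_identical(atl$p_pa["A", "C"], 0.5)
  expect_true(all(is.na(atl$ang_mean["A", "C", ])))
  # split PA observations average to 0.5
  w3 <- worm_from(rbind(c(1, 0, 0), c(0, 0, 0)), c("A", "B"), "w3")
  atl2 <- suppressMessages(build_atlas(list(w1, w3), c("A", "B")))
  expect_equal(atl2$p_pa["A", "B"], 0.5)
})

test_that("angular means are normalized averages of unit displacements", {
  w1 <- worm_from(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "B"), "w1")
  w2 <- worm_from(rbind(c(0, 0, 0), c(0, 1, 0)), c("A", "B"), "w2")
  atl <- suppressMessages(build_atlas(list(w1, w2), c("A", "B")))
  expect_equal(atl$ang_mean["A", "B", ],
               c(ap = 1, lr = 1, dv = 0) / sqrt(2))
  expect_equal(atl$ang_resultant["A", "B"], sqrt(2) / 2)
  expect_equal(atl$ang_mean["B", "A", ], -atl$ang_mean["A", "B", ])
})

test_that("each annotator contributes a separate observation", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  w <- list(cloud = point_cloud(pos, cell = 1:2, frame = "worm"),
            annotations = list(
              annotation_set("w1", "a1", 1:2, c("A", "B")),
              annotation_set("w1", "a2", 1:2, c("B", "A")),
              annotation_set("w1", "a3", 1:2, c("A", "B"))))
  atl <- suppressMessages(build_atlas(list(w), c("A", "B")))
  expect_identical(atl$counts["A", "B"], 3)
  expect_equal(atl$p_pa["A", "B"], 2 / 3)
  expect_identical(atl$provenance$annotators, c("a1", "a2", "a3"))
})

test_that("duplicate labels within one annotation are rejected by name", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  w <- list(cloud = point_cloud(pos, cell = 1:2, frame = "worm"),
            annotations = list(annotation_set("w9", "ann2", 1:2,
                                              c("A", "A"))))
  expect_error(suppressMessages(build_atlas(list(w), c("A", "B"))),
               "w9.*ann2|duplicate")
})

test_that("update_atlas pools observations exactly", {
  w1 <- worm_from(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "B"), "w1")
  w2 <- worm_from(rbind(c(0, 1, 1), c(1, 0, 0)), c("A", "B"), "w2")
  w3 <- worm_from(rbind(c(1, 0, 0), c(0, 1, 1)), c("A", "B"), "w3")
  base <- suppressMessages(build_atlas(list(w1, w2), c("A", "B")))
  upd <- suppressMessages(update_atlas(base, list(w3)))
  full <- suppressMessages(build_atlas(list(w1, w2, w3), c("A", "B")))
  expect_identical(upd$counts, full$counts)
  expect_equal(upd$p_pa, full$p_pa)
  expect_equal(upd$p_lr, full$p_lr)
  expect_equal(upd$ang_mean, full$ang_mean)
  expect_equal(upd$ang_resultant, full$ang_resultant)
  expect_identical(upd$counts["A", "B"], 3)
  expect_equal(upd$p_pa["A", "B"], 2 / 3)
  # zero new worms: identity
  upd0 <- suppressMessages(update_atlas(base, list()))
  expect_equal(upd0$p_pa, base$p_pa)
  expect_identical(upd0$counts, base$counts)
  # new label extends the universe; old pairs untouched
  w4 <- worm_from(rbind(c(0, 0, 0), c(2, 0, 0)), c("A", "D"), "w4")
  ext <- suppressMessages(update_atlas(base, list(w4)))
  expect_true("D" %in% ext$labels)
  expect_identical(ext$counts["A", "B"], base$counts["A", "B"])
  expect_identical(ext$counts["A", "D"], 1)
  expect_identical(ext$counts["B", "D"], 0)
})

test_that("atlas construction is permutation-invariant in worms and annotators", {
  coh <- tiny_cohort(n_labels = 8, n_pairs = 3, n_worms = 4, sigma = 0.8,
                     error = 0.15, seed = 21)
  a1 <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  shuffled <- rev(coh$worms)
  shuffled <- lapply(shuffled, function(w) {
    w$annotations <- rev(w$annotations); w
  })
  a2 <- suppressMessages(build_atlas(shuffled, coh$ref$labels))
  expect_equal(a1$p_pa, a2$p_pa)
  expect_equal(a1$ang_mean, a2$ang_mean)
  expect_identical(a1$counts, a2$counts)
})

test_that("probability complements hold on all observed pairs", {
  coh <- tiny_cohort(n_labels = 10, n_pairs = 4, n_worms = 5, sigma = 1,
                     dropout = 0.3, error = 0.1, seed = 22)
  atl <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  obs <- atl$counts > 0
  for (p in list(atl$p_pa, atl$p_lr, atl$p_dv))
    expect_lt(max(abs((p + t(p) - 1)[obs])), 1e-12)
})

test_that("noise-free observations are unanimous and directionally exact", {
  coh <- tiny_cohort(n_labels = 8, n_pairs = 3, n_worms = 3, sigma = 0,
                     seed = 23)
  atl <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  obs <- atl$counts > 0
  # mirrored pair members share AP and DV coordinates exactly, so those
  # pairs are genuine ties (0.5); everything else is unanimous
  expect_true(all(atl$p_pa[obs] %in% c(0, 0.5, 1)))
  mirror_free <- setdiff(atl$labels, c(coh$ref$pairs))
  expect_true(all(atl$p_pa[mirror_free, mirror_free][
    atl$counts[mirror_free, mirror_free] > 0] %in% c(0, 1)))
  expect_true(all(abs(atl$ang_resultant[obs] - 1) < 1e-9))
  # directions match the reference map exactly
  pos <- coh$ref$positions
  for (pair in list(c(1, 2), c(3, 6), c(2, 5))) {
    m <- coh$ref$labels[pair[1]]; n <- coh$ref$labels[pair[2]]
    d <- pos[n, ] - pos[m, ]
    expect_equal(unname(atl$ang_mean[m, n, ]), unname(d / sqrt(sum(d^2))),
                 tolerance = 1e-9)
  }
})

test_that("truncation restricts tables and enforces membership", {
  coh <- tiny_cohort(n_labels = 6, n_pairs = 2, n_worms = 3, seed = 24)
  atl <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  expect_equal(truncate_atlas(atl, atl$labels), atl)
  sub <- atl$labels[c(2, 4)]
  tr <- truncate_atlas(atl, sub)
  expect_identical(tr$labels, sub)
  expect_identical(tr$p_pa, atl$p_pa[sub, sub])
  expect_identical(tr$counts, atl$counts[sub, sub])
  expect_error(truncate_atlas(atl, "NOPE"), "not in atlas")
})

test_that("atlas comparison is zero on self and exact on constructed cases", {
  coh <- tiny_cohort(n_labels = 6, n_pairs = 2, n_worms = 3, sigma = 0.5,
                     seed = 25)
  atl <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  d <- compare_atlases(atl, atl)
  expect_lt(max(d$pairs$angle_deg, na.rm = TRUE), 1e-5)
  expect_equal(unname(d$means[c("d_pa", "d_lr", "d_dv")]), c(0, 0, 0))
  # constructed 90-degree angular difference and 0.75 probability difference
  wa <- worm_from(rbind(c(0, 0, 0), c(1, 0, 0)), c("A", "B"), "w1")
  wb <- worm_from(rbind(c(0, 0, 0), c(0, 1, 0)), c("A", "B"), "w1")
  a <- suppressMessages(build_atlas(list(wa), c("A", "B")))
  b <- suppressMessages(build_atlas(list(wb), c("A", "B")))
  cmp <- compare_atlases(a, b)
  expect_equal(cmp$pairs$angle_deg, 90)
  wr <- worm_from(rbind(c(1, 0, 0), c(0, 0, 0)), c("A", "B"), "w2")
  a2 <- suppressMessages(build_atlas(list(wa, wa, wa, wa), c("A", "B")))
  b2 <- suppressMessages(build_atlas(list(wa, wr, wr, wr), c("A", "B")))
  cmp2 <- compare_atlases(a2, b2)        # p_pa 1.0 vs 0.25
  expect_equal(cmp2$pairs$d_pa, 0.75)
  expect_error(compare_atlases(a, suppressMessages(
    build_atlas(list(worm_from(rbind(c(0, 0, 0), c(1, 0, 0)),
                               c("C", "D"), "w")), c("C", "D")))),
    "no label pair")
})
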