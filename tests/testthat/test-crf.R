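# small problems with exactly known potentials
two_cell_problem <- function(p_all = 1, with_ang = TRUE,
                             weights = c(pa = 1, lr = 1, dv = 1, ang = 1)) {
  # atlas built from one observation A at origin, B at (1,1,1)/sqrt(3):
  # A precedes B on every axis, direction (1,1,1)/sqrt(3)
  pos <- rbind(c(0, 0, 0), c(1, 1, 1) / sqrt(3))
  w <- list(cloud = point_cloud(pos, cell = 1:2, frame = "worm"),
            annotations = list(annotation_set("w", "a", 1:2, c("A", "B"))))
  atl <- suppressMessages(build_atlas(list(w), c("A", "B")))
  cl <- point_cloud(pos, cell = 1:2, frame = "worm")
  crf_problem(suppressMessages(extract_features(cl)), c("A", "B"), atl,
              weights = weights)
}

test_that("pairwise potentials take their analytic values", {
  prob <- two_cell_problem()
  # full agreement on all three axes and parallel angular vectors: 4
  expect_equal(pairwise_potential(prob, 1, 2, "A", "B"), 4)
  # complete contradiction: binaries all disagree, angular antiparallel: 0
  expect_equal(pairwise_potential(prob, 1, 2, "B", "A"), 0)
  expect_error(pairwise_potential(prob, 1, 2, "A", "Z"), "candidate")
  expect_error(pairwise_potential(prob, 1, 1, "A", "B"), "distinct")

  # uninformative atlas: every potential is 0.5 * sum(weights)
  atl0 <- empty_atlas(c("A", "B"))
  cl <- point_cloud(rbind(c(0, 0, 0), c(3, -1, 2)), cell = 1:2,
                    frame = "worm")
  prob0 <- crf_problem(suppressMessages(extract_features(cl)),
                       c("A", "B"), atl0)
  expect_equal(pairwise_potential(prob0, 1, 2, "A", "B"), 2)
  expect_equal(pairwise_potential(prob0, 1, 2, "B", "A"), 2)

  # reversed PA observation with otherwise uninformative tables:
  # 0 (pa) + 0.5 + 0.5 (lr, dv) + 0.5 (no angular) = 1.5
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  w1 <- list(cloud = point_cloud(pos, cell = 1:2, frame = "worm"),
             annotations = list(annotation_set("w", "a", 1:2, c("A", "B"))))
  w2 <- list(cloud = point_cloud(rbind(c(0, 0, 1), c(1, 0, 0)), cell = 1:2,
                                 frame = "worm"),
             annotations = list(annotation_set("w2", "a", 1:2,
                                               c("A", "B"))))
  atl <- suppressMessages(build_atlas(list(w1, w2), c("A", "B")))
  # test cloud: B-like cell first (reversed AP), ties on LR, mixed DV
  cl2 <- point_cloud(rbind(c(1, 0, 0.5), c(0, 0, 0.5)), cell = 1:2,
                     frame = "worm")
  prob2 <- crf_problem(suppressMessages(extract_features(cl2)),
                       c("A", "B"), atl,
                       weights = c(pa = 1, lr = 1, dv = 1, ang = 0))
  # atlas: p_pa(A,B) = 1, p_lr = 0.5 (ties), p_dv(A,B) = (0.5 + 0)/2
  # observed: cell1 after cell2 on AP -> B_pa = 1 - 1 = 0; LR and DV
  # observations are ties broken toward cell 1 -> B = p directly
  expect_equal(unname(prob2$P[1, 2, 1, 2]),
               unname(0 + atl$p_lr["A", "B"] + atl$p_dv["A", "B"]))
})

test_that("weights scale the potential families", {
  prob <- two_cell_problem(weights = c(pa = 2, lr = 0, dv = 0, ang = 3))
  expect_equal(pairwise_potential(prob, 1, 2, "A", "B"), 2 + 3)
  expect_error(crf_problem(structure(list(), class = "pairwise_features"),
                           character(0), empty_atlas("A")), "empty")
})

test_that("brute force enumerates exactly and breaks ties lexicographically", {
  prob <- two_cell_problem()
  bf <- brute_force_map(prob)
  expect_identical(bf$labels, c("A", "B"))
  expect_equal(bf$score, 4)
  # uninformative problem: first lexicographic injective assignment
  atl0 <- empty_atlas(c("A", "B", "C"))
  cl <- point_cloud(matrix(rnorm(9), 3, 3), cell = 1:3, frame = "worm")
  prob0 <- crf_problem(suppressMessages(extract_features(cl)),
                       c("A", "B", "C"), atl0)
  bf0 <- brute_force_map(prob0)
  expect_identical(bf0$labels, c("A", "B", "C"))
  expect_error(brute_force_map(prob0, cap = 2), "cap")
})

test_that("single-cell and degenerate problems behave", {
  atl0 <- empty_atlas(c("A", "B"))
  f1 <- structure(list(pa = matrix(FALSE, 1, 1), lr = matrix(FALSE, 1, 1),
                       dv = matrix(FALSE, 1, 1),
                       ang = array(NA_real_, c(1, 1, 3)), cell = 1,
                       degenerate = matrix(0, 0, 2)),
                  class = "pairwise_features")
  prob1 <- crf_problem(f1, c("A"), atl0)
  asg <- map_assign(prob1)
  expect_identical(asg$labels, "A")
  expect_equal(asg$score, 0)
})

test_that("map_assign equals the generating truth on noise-free worms", {
  coh <- tiny_cohort(n_labels = 6, n_pairs = 2, n_worms = 3, sigma = 0,
                     seed = 31)
  atl <- suppressMessages(build_atlas(coh$worms[-1], coh$ref$labels))
  w <- coh$worms[[1]]
  prob <- crf_problem(suppressMessages(extract_features(w$cloud)),
                      coh$ref$labels, atl)
  asg <- map_assign(prob)
  expect_identical(asg$labels, w$annotations[[1]]$labels)
  bf <- brute_force_map(prob)
  expect_equal(asg$score, bf$score)
})

test_that("heuristic search matches the brute-force optimum on random problems", {
  set.seed(32)
  hits <- 0
  for (t in 1:30) {
    n <- sample(3:6, 1)
    L <- n + sample(0:2, 1)
    ref <- make_reference_map(max(L, 4), 0, seed = t + 100,
                              min_separation = 2)
    cfg <- synthetic_config(jitter_sigma = 1.5, dropout = 0,
                            annotator_error = 0, seed = t + 200)
    worms <- suppressMessages(simulate_cohort(ref, cfg, 2))
    atl <- suppressMessages(build_atlas(worms, ref$labels))
    cfg2 <- cfg; cfg2$seed <- t + 300
    sw <- sample_worm(ref, cfg2)
    keep <- sort(sample(length(ref$labels), n))
    cl <- point_cloud(sw$worm_cloud$points[keep, , drop = FALSE],
                      cell = seq_len(n), frame = "worm")
    prob <- crf_problem(suppressMessages(extract_features(cl)),
                        ref$labels, atl)
    h <- map_assign(prob, seed = t, exhaustive_cap = 0)  # force heuristic
    b <- brute_force_map(prob)
    expect_false(anyDuplicated(na.omit(h$labels)) > 0)
    if (abs(h$score - b$score) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("unassigned cells appear only when cells outnumber candidates", {
  coh <- tiny_cohort(n_labels = 5, n_pairs = 2, n_worms = 2, sigma = 0,
                     seed = 33)
  atl <- suppressMessages(build_atlas(coh$worms, coh$ref$labels))
  w <- coh$worms[[1]]
  feats <- suppressMessages(extract_features(w$cloud))
  expect_error(crf_problem(feats, coh$ref$labels[1:3], atl,
                           allow_unassigned = FALSE), "allow_unassigned")
  prob <- crf_problem(feats, coh$ref$labels[1:3], atl)
  asg <- map_assign(prob)
  expect_identical(sum(is.na(asg$labels)), 2L)
  expect_identical(anyDuplicated(na.omit(asg$labels)), 0L)
})

test_that("ranked predictions are deterministic and consistent with truth", {
  coh <- tiny_cohort(n_labels = 10, n_pairs = 4, n_worms = 3, sigma = 0,
                     seed = 34)
  atl <- suppressMessages(build_atlas(coh$worms[-1], coh$ref$labels))
  w <- coh$worms[[1]]
  prob <- crf_problem(suppressMessages(extract_features(w$cloud)),
                      coh$ref$labels, atl)
  rp1 <- rank_predictions(prob, n_iterations = 30, n_removed = 2, seed = 5)
  rp2 <- rank_predictions(prob, n_iterations = 30, n_removed = 2, seed = 5)
  expect_identical(rp1, rp2)
  truth <- w$annotations[[1]]$labels
  top1 <- vapply(seq_along(prob$cells), function(i)
    rp1$ranking[[i]]$label[1], "")
  expect_identical(top1, truth)
  for (r in rp1$ranking) {
    expect_lte(sum(r$frequency), 1 + 1e-12)
    expect_true(all(diff(r$frequency) <= 0))
  }
  expect_error(rank_predictions(prob, n_removed = 10), "smaller")
})

test_that("with no removal the ensemble reproduces the best single prediction", {
  coh <- tiny_cohort(n_labels = 8, n_pairs = 3, n_worms = 3, sigma = 0.5,
                     seed = 35)
  atl <- suppressMessages(build_atlas(coh$worms[-1], coh$ref$labels))
  w <- coh$worms[[1]]
  prob <- crf_problem(suppressMessages(extract_features(w$cloud)),
                      coh$ref$labels, atl)
  best <- map_assign(prob, seed = 2)
  rp <- rank_predictions(prob, n_iterations = 25, n_removed = 0, seed = 2)
  for (i in seq_along(prob$cells)) {
    expect_identical(rp$ranking[[i]]$label[1], best$labels[i])
    expect_equal(rp$ranking[[i]]$frequency[1], 1.0)
  }
})
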