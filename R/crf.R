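# Conditional-random-field identity assignment. Cells are CRF nodes,
# candidate neuron names are states, and every cell pair carries a
# potential scoring how well the observed positional relations (PA/LR/DV
# order and displacement direction) agree with the atlas statistics for
# the hypothesized label pair. MAP inference under the one-label-per-cell
# constraint gives the best single prediction; repeated inference with
# random candidate removal gives ranked top-k predictions.

#' Assemble a CRF identity-assignment problem
#'
#' Precomputes the full pairwise-potential table
#' `P[m, n, i, j] = potential(cell i = label m, cell j = label n)` with
#' `P[m, n, i, j] = w_pa B_pa + w_lr B_lr + w_dv B_dv + w_ang A`, where
#' `B_axis` is the atlas probability that m precedes n on that axis if
#' the observed cells say i precedes j (else its complement; 0.5 for
#' atlas pairs never observed), and `A = (1 + ang_mean(m,n) .
#' ang_obs(i,j)) / 2` (0.5 when either direction is unavailable).
#'
#' @param features a `pairwise_features` from [extract_features()].
#' @param candidates a [candidate_list()] or character vector; must be a
#'   subset of `atlas$labels`.
#' @param atlas a `worm_atlas`.
#' @param weights named non-negative weights `c(pa, lr, dv, ang)`;
#'   default all 1.
#' @param allow_unassigned leave cells unlabelled when cells outnumber
#'   candidates; default exactly then.
#' @return An object of class `crf_problem`.
#' @export
crf_problem <- function(features, candidates, atlas,
                        weights = c(pa = 1, lr = 1, dv = 1, ang = 1),
                        allow_unassigned = NULL) {
  stopifnot(inherits(features, "pairwise_features"),
            inherits(atlas, "worm_atlas"))
  labels <- if (inherits(candidates, "candidate_list")) candidates$labels
            else as.character(candidates)
  if (length(labels) < 1L) stop("empty candidate list", call. = FALSE)
  if (!all(labels %in% atlas$labels))
    stop("candidates outside the atlas label set: ",
         paste(setdiff(labels, atlas$labels), collapse = ", "),
         call. = FALSE)
  w <- weights[c("pa", "lr", "dv", "ang")]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0)
    stop("weights must be named (pa, lr, dv, ang), non-negative, sum > 0",
         call. = FALSE)
  atl <- truncate_atlas(atlas, labels)
  n <- nrow(features$pa)
  L <- length(labels)
  if (is.null(allow_unassigned)) allow_unassigned <- n > L
  if (n > L && !allow_unassigned)
    stop(n, " cells but only ", L,
         " candidates; set allow_unassigned = TRUE", call. = FALSE)
  # P is augmented with a dummy state L+1 (UNASSIGNED, zero potential)
  P <- array(0, dim = c(L + 1, L + 1, n, n))
  half <- matrix(0.5, L, L); diag(half) <- 0
  am <- atl$ang_mean
  amz <- am; amz[is.na(amz)] <- 0
  has_ang <- !is.na(am[, , 1])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    b <- function(p_tab, obs_ij) if (obs_ij) p_tab else 1 - p_tab
    Bpa <- b(atl$p_pa, features$pa[i, j])
    Blr <- b(atl$p_lr, features$lr[i, j])
    Bdv <- b(atl$p_dv, features$dv[i, j])
    a_obs <- features$ang[i, j, ]
    if (anyNA(a_obs)) A <- half
    else {
      dotm <- amz[, , 1] * a_obs[1] + amz[, , 2] * a_obs[2] +
              amz[, , 3] * a_obs[3]
      A <- (1 + dotm) / 2
      A[!has_ang] <- 0.5
    }
    Pij <- w["pa"] * Bpa + w["lr"] * Blr + w["dv"] * Bdv + w["ang"] * A
    diag(Pij) <- 0                       # m = n infeasible (uniqueness)
    P[1:L, 1:L, i, j] <- Pij
    P[1:L, 1:L, j, i] <- t(Pij)
  }
  structure(list(cells = features$cell, labels = labels, atlas = atl,
                 weights = w, n_cells = n, n_labels = L, P = P,
                 allow_unassigned = allow_unassigned),
            class = "crf_problem")
}

#' @export
print.crf_problem <- function(x, ...) {
  cat(sprintf("<crf_problem> %d cells, %d candidates, weights (%s)\n",
              x$n_cells, x$n_labels,
              paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Pairwise potential for one cell pair and label pair
#'
#' The agreement score defined in [crf_problem()]; exposed for
#' inspection and testing.
#'
#' @param problem a `crf_problem`.
#' @param cell_i,cell_j distinct cell ids.
#' @param label_m,label_n distinct candidate labels.
#' @return Non-negative score (maximum `sum(weights)`).
#' @export
pairwise_potential <- function(problem, cell_i, cell_j, label_m, label_n) {
  i <- match(cell_i, problem$cells); j <- match(cell_j, problem$cells)
  m <- match(label_m, problem$labels); n <- match(label_n, problem$labels)
  if (anyNA(c(i, j))) stop("unknown cell id", call. = FALSE)
  if (anyNA(c(m, n)))
    stop("label outside the candidate list", call. = FALSE)
  if (i == j || m == n)
    stop("cells and labels must be distinct pairs", call. = FALSE)
  problem$P[m, n, i, j]
}

# objective of an assignment (integer label indices; L+1 = unassigned)
assignment_score <- function(P, lab) {
  n <- length(lab)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + P[lab[i], lab[j], i, j]
  s
}

make_assignment <- function(problem, lab_idx, score, method) {
  L <- problem$n_labels
  labs <- ifelse(lab_idx > L, NA_character_, problem$labels[lab_idx])
  if (anyDuplicated(stats::na.omit(labs)))
    stop("internal error: duplicate labels in assignment", call. = FALSE)
  structure(list(cells = problem$cells, labels = labs, score = score,
                 method = method),
            class = "crf_assignment")
}

#' @export
print.crf_assignment <- function(x, ...) {
  cat(sprintf("<crf_assignment> %d cells, objective %.4f (%s)\n",
              length(x$cells), x$score, x$method))
  invisible(x)
}

#' Exact MAP assignment by exhaustive enumeration
#'
#' Enumerates every injective cell-to-label assignment in lexicographic
#' order (cell order outer, candidate order inner) and returns the first
#' maximizer, so ties break lexicographically. A testing oracle and the
#' engine behind [map_assign()] on small problems.
#'
#' @param problem a `crf_problem` with cells <= candidates.
#' @param allowed optional logical mask over candidates.
#' @param cap maximum number of feasible assignments (default 1e6).
#' @return A `crf_assignment`.
#' @export
brute_force_map <- function(problem, allowed = NULL, cap = 1e6) {
  n <- problem$n_cells; L <- problem$n_labels
  if (is.null(allowed)) allowed <- rep(TRUE, L)
  La <- sum(allowed)
  if (n > La)
    stop("exhaustive search requires cells <= available candidates",
         call. = FALSE)
  if (prod(La - seq_len(n) + 1) > cap)
    stop("feasible assignment count exceeds cap (", format(cap), ")",
         call. = FALSE)
  P <- problem$P
  lab <- integer(n)
  used <- rep(FALSE, L)
  cand <- which(allowed)
  best_lab <- NULL; best_score <- -Inf
  rec <- function(i, acc) {
    if (i > n) {
      if (acc > best_score + 1e-12) {
        best_score <<- acc; best_lab <<- lab[seq_len(n)]
      }
      return(invisible())
    }
    for (m in cand) {
      if (used[m]) next
      inc <- 0
      if (i > 1) {
        jj <- seq_len(i - 1)
        inc <- sum(P[cbind(lab[jj], m, jj, i)])
      }
      lab[i] <<- m; used[m] <<- TRUE
      rec(i + 1, acc + inc)
      used[m] <<- FALSE
    }
  }
  rec(1L, 0)
  make_assignment(problem, best_lab, best_score, "exhaustive")
}

# greedy construction + best-improvement local search (reassign + swap)
heuristic_map <- function(problem, allowed, init = NULL, max_iter = 1000L) {
  P <- problem$P
  n <- problem$n_cells; L <- problem$n_labels
  dummy <- L + 1L
  cand <- which(allowed)
  if (is.null(init)) {
    # optimistic greedy: upper bound each undecided pair by its best case
    M <- matrix(0, L + 1, n)             # M[m, i] = sum_j max_n P[m,n,i,j]
    for (i in seq_len(n)) {
      mx <- rep(0, L + 1)
      for (j in seq_len(n)) {
        if (j == i) next
        mx <- mx + apply(P[, c(cand, dummy), i, j, drop = FALSE], 1, max)
      }
      M[, i] <- mx
    }
    lab <- rep(dummy, n)
    undecided <- rep(TRUE, n)
    free <- rep(FALSE, L + 1); free[cand] <- TRUE
    for (step in seq_len(min(n, length(cand)))) {
      best <- c(-Inf, 0, 0)
      for (i in which(undecided)) {
        asn <- which(!undecided)
        fixed <- if (length(asn))
          rowSums(matrix(P[cbind(rep(seq_len(L + 1), length(asn)),
                                 rep(lab[asn], each = L + 1),
                                 rep(i, (L + 1) * length(asn)),
                                 rep(asn, each = L + 1))],
                         L + 1, length(asn)))
          else rep(0, L + 1)
        g <- fixed + M[, i] * (sum(undecided) - 1) / max(1, n - 1)
        g[!free] <- -Inf
        mi <- which.max(g)
        if (g[mi] > best[1]) best <- c(g[mi], i, mi)
      }
      i <- best[2]; m <- best[3]
      lab[i] <- m; undecided[i] <- FALSE; free[m] <- FALSE
    }
  } else lab <- init
  # local search
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    # R[[i]][m, j] = P[m, lab[j], i, j]; T[[i]][m] = sum_j R[[i]][m, j]
    Rl <- vector("list", n); Tm <- matrix(0, L + 1, n)
    for (i in seq_len(n)) {
      jj <- setdiff(seq_len(n), i)
      Ri <- matrix(P[cbind(rep(seq_len(L + 1), length(jj)),
                           rep(lab[jj], each = L + 1),
                           rep(i, (L + 1) * length(jj)),
                           rep(jj, each = L + 1))], L + 1, length(jj))
      colnames(Ri) <- as.character(jj)
      Rl[[i]] <- Ri
      Tm[, i] <- rowSums(Ri)
    }
    used <- rep(FALSE, L + 1); used[lab[lab <= L]] <- TRUE
    free_lab <- which(allowed & !used[seq_len(L)])
    best_delta <- 1e-9; move <- NULL
    for (i in seq_len(n)) {
      cur <- Tm[lab[i], i]
      # reassignment to a free label (or to UNASSIGNED if permitted)
      opts <- free_lab
      if (problem$allow_unassigned && lab[i] <= L) opts <- c(opts, dummy)
      for (m in opts) {
        d <- Tm[m, i] - cur
        if (d > best_delta) { best_delta <- d; move <- c(1, i, m) }
      }
      # swaps with later cells
      if (i < n) for (j in (i + 1):n) {
        li <- lab[i]; lj <- lab[j]
        if (li == lj) next                 # both unassigned
        cj <- as.character(j); ci <- as.character(i)
        d <- (Tm[lj, i] - Rl[[i]][lj, cj]) + (Tm[li, j] - Rl[[j]][li, ci]) -
             (Tm[li, i] - Rl[[i]][li, cj]) - (Tm[lj, j] - Rl[[j]][lj, ci]) +
             P[lj, li, i, j] - P[li, lj, i, j]
        if (d > best_delta) { best_delta <- d; move <- c(2, i, j) }
      }
    }
    if (is.null(move)) break
    if (move[1] == 1) lab[move[2]] <- move[3]
    else { tmp <- lab[move[2]]; lab[move[2]] <- lab[move[3]]; lab[move[3]] <- tmp }
  }
  list(lab = lab, score = assignment_score(P, lab))
}

#' MAP identity assignment
#'
#' Maximizes the sum of pairwise potentials over all cell pairs subject
#' to label uniqueness. Problems whose feasible-assignment count is at
#' most `exhaustive_cap` are solved exactly by enumeration; larger ones
#' by greedy construction followed by single-reassignment / pairwise-swap
#' hill climbing with seeded random restarts (deterministic for a fixed
#' problem and seed).
#'
#' @param problem a `crf_problem`.
#' @param seed integer seed for the restart randomization.
#' @param restarts number of hill-climbing starts (first is greedy, rest
#'   random permutations).
#' @param max_iter local-search move cap per start.
#' @param exhaustive_cap feasible-count threshold for exact search.
#' @param allowed optional logical mask over candidates (used by the
#'   ranked-prediction ensemble).
#' @return A `crf_assignment`.
#' @export
map_assign <- function(problem, seed = 1L, restarts = 5L,
                       max_iter = 1000L, exhaustive_cap = 1e5,
                       allowed = NULL) {
  stopifnot(inherits(problem, "crf_problem"))
  n <- problem$n_cells; L <- problem$n_labels
  if (is.null(allowed)) allowed <- rep(TRUE, L)
  La <- sum(allowed)
  if (La < 1L) stop("no candidates available", call. = FALSE)
  if (n <= La && prod(La - seq_len(n) + 1) <= exhaustive_cap)
    return(brute_force_map(problem, allowed, cap = exhaustive_cap))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  dummy <- L + 1L
  cand <- which(allowed)
  best <- heuristic_map(problem, allowed, init = NULL, max_iter = max_iter)
  for (r in seq_len(max(0L, restarts - 1L))) {
    k <- min(n, La)
    init <- rep(dummy, n)
    init[sample.int(n, k)] <- sample(cand, k)
    res <- heuristic_map(problem, allowed, init = init, max_iter = max_iter)
    if (res$score > best$score + 1e-12) best <- res
  }
  make_assignment(problem, best$lab, best$score, "greedy+local")
}

#' Ranked top-k predictions by randomized candidate removal
#'
#' Runs [map_assign()] `n_iterations` times, each with `n_removed`
#' candidates removed uniformly at random (fresh draw per iteration), and
#' reports, per cell, the label frequencies across iterations in
#' descending order. The top-k prediction for a cell is the first k
#' entries. Distinct from the best single prediction, which is one run
#' on the full candidate list.
#'
#' @param problem a `crf_problem`.
#' @param n_iterations ensemble size (default 100).
#' @param n_removed candidates removed per iteration; default
#'   `max(1, floor(0.1 * n_candidates))`; must be < number of candidates.
#' @param seed integer seed driving all removal draws.
#' @param restarts,max_iter,exhaustive_cap passed to [map_assign()].
#' @return An object of class `ranked_prediction`: per-cell data frames
#'   `ranking` (label, frequency), plus `n_iterations`, `n_removed`,
#'   `seed`.
#' @export
rank_predictions <- function(problem, n_iterations = 100L, n_removed = NULL,
                             seed = 1L, restarts = 5L, max_iter = 1000L,
                             exhaustive_cap = 1e5) {
  stopifnot(inherits(problem, "crf_problem"))
  L <- problem$n_labels
  if (is.null(n_removed)) n_removed <- max(1L, floor(0.1 * L))
  if (n_removed >= L)
    stop("n_removed must be smaller than the candidate count", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  removal_seeds <- sample.int(.Machine$integer.max, n_iterations)
  n <- problem$n_cells
  counts <- matrix(0L, n, L)
  # randomness enters only through candidate removal: the solver seed is
  # fixed, so with n_removed = 0 every iteration reproduces the best
  # single prediction and only one solve is needed
  n_solves <- if (n_removed == 0L) 1L else n_iterations
  for (t in seq_len(n_solves)) {
    allowed <- rep(TRUE, L)
    if (n_removed > 0) {
      set.seed(removal_seeds[t])
      allowed[sample.int(L, n_removed)] <- FALSE
    }
    asg <- map_assign(problem, seed = seed, restarts = restarts,
                      max_iter = max_iter, exhaustive_cap = exhaustive_cap,
                      allowed = allowed)
    hit <- !is.na(asg$labels)
    idx <- match(asg$labels[hit], problem$labels)
    mult <- if (n_removed == 0L) n_iterations else 1L
    counts[cbind(which(hit), idx)] <- counts[cbind(which(hit), idx)] + mult
  }
  ranking <- lapply(seq_len(n), function(i) {
    f <- counts[i, ] / n_iterations
    keep <- which(f > 0)
    o <- keep[order(-f[keep], keep)]     # ties by candidate order
    data.frame(label = problem$labels[o], frequency = f[o],
               stringsAsFactors = FALSE)
  })
  structure(list(cells = problem$cells, ranking = ranking,
                 n_iterations = n_iterations, n_removed = n_removed,
                 seed = seed),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("<ranked_prediction> %d cells, %d iterations, %d removed/iter\n",
              length(x$cells), x$n_iterations, x$n_removed))
  invisible(x)
}

#' Top-k labels for one cell of a ranked prediction
#'
#' @param prediction a `ranked_prediction`.
#' @param cell a cell id.
#' @param k how many labels.
#' @return Character vector (length <= k).
#' @export
top_k_labels <- function(prediction, cell, k = 3L) {
  i <- match(cell, prediction$cells)
  if (is.na(i)) stop("unknown cell id", call. = FALSE)
  utils::head(prediction$ranking[[i]]$label, k)
}
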