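# Accuracy evaluation. Ground truth for real data is the consensus of
# three human annotators (a label at least two agree on); accuracy is
# "correspondence": the fraction of non-omitted cells whose predicted
# label matches the consensus. All headline numbers come from
# leave-one-out cross-validation so the tested worm never informs its
# own atlas.

#' Consensus labels from multiple annotators
#'
#' In the default strict mode exactly three annotation sets are required:
#' a cell's consensus is any label proposed by at least two annotators;
#' cells on which all three disagree are omitted from scoring. With
#' `strict = FALSE` any number (>= 2) of annotators is accepted and the
#' rule generalizes to plurality-with-at-least-2-votes.
#'
#' @param annotations list of [annotation_set()] objects covering the
#'   same cell index set.
#' @param strict require exactly 3 annotators (default).
#' @return An object of class `consensus_labels`: `cells`, `labels`
#'   (consensus or `NA`), `omitted` (cell ids with full disagreement).
#' @export
consensus_labels <- function(annotations, strict = TRUE) {
  na <- length(annotations)
  if (strict && na != 3L)
    stop("strict consensus requires exactly 3 annotation sets (got ", na,
         "); use strict = FALSE for the generalized rule", call. = FALSE)
  if (na < 2L) stop("need >= 2 annotators for a consensus", call. = FALSE)
  cells <- sort(unique(unlist(lapply(annotations, `[[`, "cells"))))
  for (a in annotations)
    if (!setequal(a$cells, cells))
      stop("annotation sets must cover the same cell index set",
           call. = FALSE)
  lab_mat <- vapply(annotations, function(a)
    a$labels[match(cells, a$cells)], character(length(cells)))
  lab_mat <- matrix(lab_mat, nrow = length(cells))
  cons <- rep(NA_character_, length(cells))
  for (r in seq_along(cells)) {
    votes <- table(stats::na.omit(lab_mat[r, ]))
    if (length(votes) && max(votes) >= 2L)
      cons[r] <- names(votes)[which.max(votes)]
  }
  omitted <- cells[is.na(cons)]
  structure(list(cells = cells, labels = cons, omitted = omitted),
            class = "consensus_labels")
}

#' @export
print.consensus_labels <- function(x, ...) {
  cat(sprintf("<consensus_labels> %d cells, %d omitted (full disagreement)\n",
              length(x$cells), length(x$omitted)))
  invisible(x)
}

predicted_topk <- function(prediction, cell, k) {
  if (inherits(prediction, "crf_assignment")) {
    i <- match(cell, prediction$cells)
    if (is.na(i)) NA_character_ else prediction$labels[i]
  } else if (inherits(prediction, "ranked_prediction")) {
    top_k_labels(prediction, cell, k)
  } else stop("unsupported prediction object", call. = FALSE)
}

#' Correspondence of a prediction to consensus labels
#'
#' The fraction of non-omitted cells whose consensus label equals the
#' best-single label (for a `crf_assignment`) or appears among the top-k
#' ranked labels (for a `ranked_prediction`). Unpredicted (UNASSIGNED)
#' cells count as mismatches.
#'
#' @param prediction a `crf_assignment` or `ranked_prediction`.
#' @param consensus a [consensus_labels()].
#' @param k ranked-mode depth; ignored for best-single predictions.
#' @return Fraction in [0, 1].
#' @export
correspondence <- function(prediction, consensus, k = 1L) {
  stopifnot(inherits(consensus, "consensus_labels"))
  scored <- consensus$cells[!is.na(consensus$labels)]
  if (length(scored) == 0L)
    stop("no non-omitted cells; correspondence undefined", call. = FALSE)
  hit <- vapply(seq_along(scored), function(ix) {
    truth <- consensus$labels[match(scored[ix], consensus$cells)]
    truth %in% predicted_topk(prediction, scored[ix], k)
  }, logical(1))
  mean(hit)
}

#' Leave-one-out cross-validated accuracy
#'
#' For each worm, builds an atlas from all other worms (every annotator
#' counted separately), predicts identities for the held-out worm, and
#' scores against that worm's consensus labels.
#'
#' @param worms list of worms as in [build_atlas()]: each a list with
#'   `cloud` (worm-frame [point_cloud()]) and `annotations`.
#' @param candidates a [candidate_list()] or character vector.
#' @param mode `"best_single"` or `"topk"`.
#' @param k ranked depth when `mode = "topk"`.
#' @param weights potential weights, see [crf_problem()].
#' @param n_iterations,n_removed ranked-ensemble settings.
#' @param seed,restarts,exhaustive_cap inference settings.
#' @param strict_consensus passed to [consensus_labels()].
#' @return A data frame with one row per worm: `worm`, `mode`,
#'   `correspondence`, `n_cells`, `n_omitted`; the per-worm predictions
#'   and consensus objects are attached as attributes `predictions` and
#'   `consensus`.
#' @export
loocv <- function(worms, candidates, mode = c("best_single", "topk"),
                  k = 3L, weights = c(pa = 1, lr = 1, dv = 1, ang = 1),
                  n_iterations = 100L, n_removed = NULL, seed = 1L,
                  restarts = 5L, exhaustive_cap = 1e5,
                  strict_consensus = TRUE) {
  mode <- match.arg(mode)
  if (length(worms) < 2L)
    stop("leave-one-out cross-validation needs >= 2 worms", call. = FALSE)
  preds <- vector("list", length(worms))
  conss <- vector("list", length(worms))
  rows <- vector("list", length(worms))
  for (wi in seq_along(worms)) {
    atl <- build_atlas(worms[-wi], candidates)
    w <- worms[[wi]]
    feats <- extract_features(w$cloud)
    prob <- crf_problem(feats, candidates, atl, weights = weights)
    pred <- if (mode == "best_single")
      map_assign(prob, seed = seed, restarts = restarts,
                 exhaustive_cap = exhaustive_cap)
    else
      rank_predictions(prob, n_iterations = n_iterations,
                       n_removed = n_removed, seed = seed,
                       restarts = restarts, exhaustive_cap = exhaustive_cap)
    cons <- consensus_labels(w$annotations, strict = strict_consensus)
    preds[[wi]] <- pred; conss[[wi]] <- cons
    worm_id <- if (!is.null(w$id)) w$id else
      if (length(w$annotations)) w$annotations[[1]]$worm else wi
    rows[[wi]] <- data.frame(
      worm = worm_id, mode = if (mode == "topk") paste0("top", k) else mode,
      correspondence = correspondence(pred, cons, k = k),
      n_cells = length(cons$cells), n_omitted = length(cons$omitted),
      stringsAsFactors = FALSE)
    stage_log("loocv: worm %s correspondence %.3f", format(worm_id),
              rows[[wi]]$correspondence)
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- preds
  attr(out, "consensus") <- conss
  out
}

#' Per-neuron automatic accuracy and manual agreement
#'
#' For every neuron label: the fraction of its consensus occurrences the
#' automatic pipeline labelled correctly, and a manual-agreement score —
#' among cells where any annotator proposed the label, the fraction
#' where at least two did. Labels never observed are absent from the
#' result.
#'
#' @param predictions list of `crf_assignment`/`ranked_prediction`, one
#'   per worm (e.g. `attr(loocv_result, "predictions")`).
#' @param annotation_sets list (per worm) of lists of [annotation_set()].
#' @param k ranked depth for counting a prediction as correct.
#' @param strict passed to [consensus_labels()].
#' @return Data frame: `label`, `n`, `auto_accuracy`, `manual_agreement`.
#' @export
per_neuron_accuracy <- function(predictions, annotation_sets, k = 1L,
                                strict = TRUE) {
  stopifnot(length(predictions) == length(annotation_sets))
  acc_n <- list(); acc_hit <- list(); prop_n <- list(); prop_agree <- list()
  bump <- function(env, lab, by = 1) {
    cur <- if (is.null(env[[lab]])) 0 else env[[lab]]
    cur + by
  }
  for (wi in seq_along(predictions)) {
    cons <- consensus_labels(annotation_sets[[wi]], strict = strict)
    lab_mat <- vapply(annotation_sets[[wi]], function(a)
      a$labels[match(cons$cells, a$cells)], character(length(cons$cells)))
    lab_mat <- matrix(lab_mat, nrow = length(cons$cells))
    for (r in seq_along(cons$cells)) {
      cell <- cons$cells[r]
      truth <- cons$labels[r]
      if (!is.na(truth)) {
        acc_n[[truth]] <- bump(acc_n, truth)
        ok <- truth %in% predicted_topk(predictions[[wi]], cell, k)
        acc_hit[[truth]] <- bump(acc_hit, truth, as.numeric(ok))
      }
      votes <- table(stats::na.omit(lab_mat[r, ]))
      for (lab in names(votes)) {
        prop_n[[lab]] <- bump(prop_n, lab)
        prop_agree[[lab]] <- bump(prop_agree, lab,
                                  as.numeric(votes[[lab]] >= 2))
      }
    }
  }
  labels <- sort(unique(c(names(acc_n), names(prop_n))))
  data.frame(
    label = labels,
    n = vapply(labels, function(l) if (is.null(acc_n[[l]])) 0 else acc_n[[l]],
               0),
    auto_accuracy = vapply(labels, function(l)
      if (is.null(acc_n[[l]])) NA_real_ else
        (if (is.null(acc_hit[[l]])) 0 else acc_hit[[l]]) / acc_n[[l]], 0),
    manual_agreement = vapply(labels, function(l)
      if (is.null(prop_n[[l]])) NA_real_ else
        (if (is.null(prop_agree[[l]])) 0 else prop_agree[[l]]) / prop_n[[l]],
      0),
    stringsAsFactors = FALSE, row.names = NULL)
}
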