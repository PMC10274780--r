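# Probabilistic positional atlas: for every ordered label pair (m, n),
# the probability that neuron m precedes neuron n along each body axis,
# the mean unit displacement direction m -> n, and how often the pair was
# co-observed. Built by pooling annotated worm-frame point clouds; each
# annotator's labelling of a worm counts as a separate observation, so
# annotator disagreement widens the statistics instead of being voted
# away.

WORMID_CONVENTION <- "precedes = smaller coordinate along +AP/+LR/+DV"

new_atlas <- function(labels, counts, s_pa, s_lr, s_dv, ang_sum,
                      provenance) {
  n <- length(labels)
  p_of <- function(s) {
    p <- matrix(0.5, n, n, dimnames = list(labels, labels))
    obs <- counts > 0
    p[obs] <- s[obs] / counts[obs]
    diag(p) <- 0.5
    p
  }
  res <- matrix(0, n, n, dimnames = list(labels, labels))
  am <- array(NA_real_, dim = c(n, n, 3),
              dimnames = list(labels, labels, c("ap", "lr", "dv")))
  len <- sqrt(ang_sum[, , 1]^2 + ang_sum[, , 2]^2 + ang_sum[, , 3]^2)
  obs <- counts > 0 & len > 1e-12
  res[obs] <- len[obs] / counts[obs]
  for (k in 1:3) {
    a <- am[, , k]
    a[obs] <- ang_sum[, , k][obs] / len[obs]
    am[, , k] <- a
  }
  structure(list(convention = WORMID_CONVENTION, labels = labels,
                 counts = counts, p_pa = p_of(s_pa), p_lr = p_of(s_lr),
                 p_dv = p_of(s_dv), ang_mean = am, ang_resultant = res,
                 provenance = provenance),
            class = "worm_atlas")
}

validate_atlas <- function(atlas) {
  for (p in c("p_pa", "p_lr", "p_dv")) {
    m <- atlas[[p]]
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("atlas ", p, " outside [0, 1]", call. = FALSE)
    obs <- atlas$counts > 0
    bad <- abs(m + t(m) - 1) > 1e-9 & obs
    diag(bad) <- FALSE
    if (any(bad))
      stop("atlas ", p, " violates p(m,n) + p(n,m) = 1 on observed pairs",
           call. = FALSE)
  }
  if (any(abs(atlas$counts - t(atlas$counts)) > 0))
    stop("atlas counts not symmetric", call. = FALSE)
  invisible(atlas)
}

#' @export
print.worm_atlas <- function(x, ...) {
  cat(sprintf("<worm_atlas> %d labels, %d observed pairs, %s dataset(s)\n",
              length(x$labels), sum(x$counts[upper.tri(x$counts)] > 0),
              format(x$provenance$n_datasets)))
  invisible(x)
}

#' An empty atlas over a candidate set
#'
#' All pair probabilities at the uninformative default 0.5, no angular
#' information, zero counts. Useful as the base of [update_atlas()].
#'
#' @param candidates a [candidate_list()] or character vector of labels.
#' @return A `worm_atlas`.
#' @export
empty_atlas <- function(candidates) {
  labels <- if (inherits(candidates, "candidate_list")) candidates$labels
            else as.character(candidates)
  n <- length(labels)
  z <- matrix(0, n, n, dimnames = list(labels, labels))
  new_atlas(labels, z, z, z, z, array(0, dim = c(n, n, 3)),
            provenance = list(n_datasets = 0, annotators = character(0)))
}

# sufficient statistics of one annotation on one worm-frame cloud:
# per ordered pair, precedes-indicator sums per axis and unit-vector sums
annotation_stats <- function(cloud, annotation, labels) {
  pts <- cloud_points(cloud)
  ids <- if (inherits(cloud, "point_cloud")) cloud$cell
         else seq_len(nrow(pts))
  keep <- !is.na(annotation$labels) & annotation$labels %in% labels
  cells <- annotation$cells[keep]
  labs <- annotation$labels[keep]
  if (anyDuplicated(labs))
    stop(sprintf("duplicate label(s) %s in annotation of worm '%s' by '%s'",
                 paste(unique(labs[duplicated(labs)]), collapse = ", "),
                 annotation$worm, annotation$annotator), call. = FALSE)
  row <- match(cells, ids)
  if (anyNA(row))
    stop(sprintf("annotation of worm '%s' by '%s' references unknown cell(s)",
                 annotation$worm, annotation$annotator), call. = FALSE)
  li <- match(labs, labels)
  k <- length(li)
  n <- length(labels)
  z <- matrix(0, n, n)
  out <- list(counts = z, s_pa = z, s_lr = z, s_dv = z,
              ang_sum = array(0, dim = c(n, n, 3)))
  if (k < 2L) return(out)
  P <- pts[row, , drop = FALSE]
  tol <- 1e-12
  ind <- function(coord) {
    d <- outer(coord, coord, "-")       # d[a,b] = coord_a - coord_b
    i <- (d < -tol) + 0.5 * (abs(d) < tol)  # ties split so p + p' = 1
    diag(i) <- 0
    i
  }
  off <- !diag(TRUE, k)
  idx <- cbind(rep(li, times = k), rep(li, each = k))[c(off), , drop = FALSE]
  put <- function(m, v) { m[idx] <- m[idx] + v[c(off)]; m }
  out$counts <- put(z, (off * 1))
  out$s_pa <- put(z, ind(P[, 1]))
  out$s_lr <- put(z, ind(P[, 2]))
  out$s_dv <- put(z, ind(P[, 3]))
  D <- array(0, dim = c(k, k, 3))
  for (ax in 1:3) D[, , ax] <- outer(P[, ax], P[, ax], function(a, b) b - a)
  nrm <- sqrt(D[, , 1]^2 + D[, , 2]^2 + D[, , 3]^2)
  nrm[nrm < tol] <- Inf                  # coincident cells: zero direction
  for (ax in 1:3) {
    s <- matrix(0, n, n)
    s[idx] <- s[idx] + (D[, , ax] / nrm)[c(off)]
    out$ang_sum[, , ax] <- s
  }
  out
}

#' Build a positional atlas from annotated worms
#'
#' @param annotated_worms list of worms; each element is a list with
#'   `cloud` (a worm-frame [point_cloud()]) and `annotations` (a list of
#'   [annotation_set()] objects for that worm). Every annotator's
#'   labelling contributes as a separate observation.
#' @param candidates a [candidate_list()] or character vector — the label
#'   universe of the atlas. Annotation labels outside it are ignored.
#' @return A `worm_atlas`: pair probabilities `p_pa`/`p_lr`/`p_dv`
#'   (default 0.5 where never co-observed), mean unit displacement
#'   directions `ang_mean` with resultant lengths, symmetric `counts`,
#'   and provenance.
#' @export
build_atlas <- function(annotated_worms, candidates) {
  update_atlas(empty_atlas(candidates), annotated_worms)
}

#' Update an atlas with new annotated worms
#'
#' Because the atlas stores observation counts, updating is exact:
#' `update_atlas(empty_atlas(c), worms)` equals `build_atlas(worms, c)`,
#' and updating a data-driven base atlas pools the observations. Pairs
#' untouched by the new data keep the base values; labels absent from the
#' base universe are appended and initialized from the new data alone.
#'
#' @param base a `worm_atlas`.
#' @param new_annotated_worms as in [build_atlas()].
#' @param convention sign-convention tag of the new data; must match the
#'   base atlas.
#' @return A `worm_atlas`.
#' @export
update_atlas <- function(base, new_annotated_worms,
                         convention = WORMID_CONVENTION) {
  stopifnot(inherits(base, "worm_atlas"))
  if (!identical(base$convention, convention))
    stop("sign-convention mismatch between base atlas and new data",
         call. = FALSE)
  new_labels <- unique(unlist(lapply(new_annotated_worms, function(w)
    unlist(lapply(w$annotations, function(a) a$labels[!is.na(a$labels)])))))
  labels <- c(base$labels, setdiff(new_labels, base$labels))
  n <- length(labels)
  grow <- function(m, fill = 0) {
    out <- matrix(fill, n, n, dimnames = list(labels, labels))
    out[seq_along(base$labels), seq_along(base$labels)] <- m
    out
  }
  counts <- grow(base$counts)
  # recover precede-sums and angular vector sums from the stored atlas
  s_pa <- grow(base$p_pa * base$counts)
  s_lr <- grow(base$p_lr * base$counts)
  s_dv <- grow(base$p_dv * base$counts)
  ang_sum <- array(0, dim = c(n, n, 3))
  nb <- length(base$labels)
  for (ax in 1:3) {
    s <- matrix(0, n, n)
    contrib <- base$ang_mean[, , ax] * base$ang_resultant * base$counts
    contrib[is.na(contrib)] <- 0
    s[seq_len(nb), seq_len(nb)] <- contrib
    ang_sum[, , ax] <- s
  }
  annotators <- base$provenance$annotators
  n_new <- 0
  for (w in new_annotated_worms) {
    for (a in w$annotations) {
      st <- annotation_stats(w$cloud, a, labels)
      counts <- counts + st$counts
      s_pa <- s_pa + st$s_pa; s_lr <- s_lr + st$s_lr; s_dv <- s_dv + st$s_dv
      ang_sum <- ang_sum + st$ang_sum
      annotators <- union(annotators, a$annotator)
    }
    n_new <- n_new + 1
  }
  atl <- new_atlas(labels, counts, s_pa, s_lr, s_dv, ang_sum,
                   provenance = list(
                     n_datasets = base$provenance$n_datasets + n_new,
                     annotators = annotators))
  validate_atlas(atl)
  stage_log("atlas: %d labels, %d dataset(s), %d annotator(s)",
            n, atl$provenance$n_datasets, length(annotators))
  atl
}

#' Restrict an atlas to a label subset
#'
#' Used to exclude candidates irrelevant for a strain (e.g. keep only the
#' 37 reporter-expressing neurons) before inference. Counts and
#' probabilities of the retained pairs are untouched.
#'
#' @param atlas a `worm_atlas`.
#' @param sublist labels to keep (subset of `atlas$labels`), or a
#'   [candidate_list()].
#' @return A `worm_atlas` over `sublist`.
#' @export
truncate_atlas <- function(atlas, sublist) {
  stopifnot(inherits(atlas, "worm_atlas"))
  if (inherits(sublist, "candidate_list")) sublist <- sublist$labels
  missing <- setdiff(sublist, atlas$labels)
  if (length(missing))
    stop("label(s) not in atlas: ", paste(missing, collapse = ", "),
         call. = FALSE)
  i <- match(sublist, atlas$labels)
  out <- atlas
  out$labels <- atlas$labels[i]
  for (f in c("counts", "p_pa", "p_lr", "p_dv", "ang_resultant"))
    out[[f]] <- atlas[[f]][i, i, drop = FALSE]
  out$ang_mean <- atlas$ang_mean[i, i, , drop = FALSE]
  out
}

#' Compare two atlases pair by pair
#'
#' Over the label pairs observed in both atlases: the angle between the
#' mean displacement directions (degrees) and the absolute difference of
#' the PA/LR/DV precede-probabilities. Summarized by their means; the
#' full per-pair distributions are returned for plotting or testing.
#'
#' @param a,b `worm_atlas` objects.
#' @return A list with `pairs` (data frame: label pair, `angle_deg`,
#'   `d_pa`, `d_lr`, `d_dv`) and `means` (named vector).
#' @export
compare_atlases <- function(a, b) {
  shared <- intersect(a$labels, b$labels)
  ia <- match(shared, a$labels); ib <- match(shared, b$labels)
  ca <- a$counts[ia, ia] > 0; cb <- b$counts[ib, ib] > 0
  obs <- which(ca & cb & upper.tri(ca), arr.ind = TRUE)
  if (nrow(obs) == 0L)
    stop("no label pair observed in both atlases", call. = FALSE)
  va <- a$ang_mean[ia, ia, , drop = FALSE]
  vb <- b$ang_mean[ib, ib, , drop = FALSE]
  rows <- lapply(seq_len(nrow(obs)), function(r) {
    i <- obs[r, 1]; j <- obs[r, 2]
    u <- va[i, j, ]; v <- vb[i, j, ]
    ang <- if (anyNA(u) || anyNA(v)) NA_real_
           else acos(max(-1, min(1, sum(u * v)))) * 180 / pi
    data.frame(label_m = shared[i], label_n = shared[j], angle_deg = ang,
               d_pa = abs(a$p_pa[ia[i], ia[j]] - b$p_pa[ib[i], ib[j]]),
               d_lr = abs(a$p_lr[ia[i], ia[j]] - b$p_lr[ib[i], ib[j]]),
               d_dv = abs(a$p_dv[ia[i], ia[j]] - b$p_dv[ib[i], ib[j]]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       means = c(angle_deg = mean(pairs$angle_deg, na.rm = TRUE),
                 d_pa = mean(pairs$d_pa), d_lr = mean(pairs$d_lr),
                 d_dv = mean(pairs$d_dv)))
}
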