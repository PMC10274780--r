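#' Construct a 3D fluorescence volume
#'
#' A `worm_volume` holds one channel of a 3D image stack as an array in
#' (z, y, x) order together with the physical voxel spacing in micrometres.
#' All downstream geometry (centroids, covariances, axes) is computed in
#' micrometres, so anisotropic spacing (e.g. 0.3 um in z vs 0.4 um in x/y)
#' is accounted for once, here.
#'
#' @param data numeric 3D array, dimensions (z, y, x); finite, non-negative.
#' @param spacing numeric length-3, voxel size in um for (z, y, x); all > 0.
#' @param channel `"red"` (cell nuclei) or `"green"` (autofluorescence).
#' @return An object of class `worm_volume`.
#' @export
worm_volume <- function(data, spacing, channel = c("red", "green")) {
  channel <- match.arg(channel)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (z, y, x) in um", call. = FALSE)
  structure(list(data = data, spacing = spacing, channel = channel),
            class = "worm_volume")
}

#' @export
print.worm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<worm_volume> %s channel, %d x %d x %d voxels (z,y,x), spacing %s um\n",
              x$channel, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Read a multi-page TIFF stack as a volume
#'
#' Pages of the TIFF are stacked along z. Intensities are returned on the
#' original integer scale (16-bit grayscale assumed; values in 0..65535).
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing voxel spacing (z, y, x) in um; required, since stacks
#'   exported by acquisition software frequently lack usable pixel-size tags.
#' @param channel channel tag, `"red"` or `"green"`.
#' @return A [worm_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing, channel = c("red", "green")) {
  channel <- match.arg(channel)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop("unreadable TIFF '", path, "': ", conditionMessage(e),
                           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("stack has ", length(pages),
         " page(s); a volume needs >= 2 z planes", call. = FALSE)
  if (length(dim(pages[[1]])) != 2L)
    stop("TIFF pages must be single-channel grayscale", call. = FALSE)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  # readTIFF rescales integer data to [0,1]; restore the 16-bit scale
  arr <- round(arr * 65535)
  worm_volume(arr, spacing, channel)
}

#' Write a volume as a multi-page 16-bit TIFF
#'
#' Intensities must lie in [0, 65535]; integer values round-trip exactly
#' through [read_volume()].
#'
#' @param volume a [worm_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "worm_volume"))
  if (max(volume$data) > 65535 || min(volume$data) < 0)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF output",
         call. = FALSE)
  nz <- dim(volume$data)[1]
  pages <- lapply(seq_len(nz), function(z) volume$data[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Construct a point cloud of cell positions
#'
#' @param points numeric matrix, one row per cell, columns x, y, z in um.
#' @param intensity optional numeric vector of per-cell intensities.
#' @param cell optional cell identifiers (default `1:n`).
#' @param frame `"image"` (microscope frame) or `"worm"` (body-axes frame,
#'   columns then read AP, LR, DV).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, intensity = NULL, cell = NULL,
                        frame = c("image", "worm")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("point coordinates must be finite", call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  if (is.null(cell)) cell <- seq_len(n)
  if (length(cell) != n) stop("cell ids must match point count", call. = FALSE)
  if (!is.null(intensity) && length(intensity) != n)
    stop("intensity length must match point count", call. = FALSE)
  structure(list(points = points, intensity = intensity,
                 cell = cell, frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, %s frame%s\n", nrow(x$points), x$frame,
              if (is.null(x$intensity)) "" else ", with intensities"))
  invisible(x)
}

fmt17 <- function(x) {
  # full-precision decimal text; write.csv's 15 digits would be lossy
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Read / write point clouds as CSV
#'
#' The on-disk format is a CSV with header `cell,x,y,z[,intensity]`,
#' coordinates in um. Coordinates are stored with 17 significant digits so
#' a write/read cycle is bit-exact. Row order is preserved.
#'
#' @param path CSV path.
#' @param frame frame tag to stamp on the cloud (`"image"` or `"worm"`).
#' @return `read_point_cloud`: a [point_cloud()]. `write_point_cloud`:
#'   `path`, invisibly.
#' @export
read_point_cloud <- function(path, frame = c("image", "worm")) {
  frame <- match.arg(frame)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("point-cloud CSV must have columns x, y, z (missing: ",
         paste(setdiff(need, names(df)), collapse = ", "), ")", call. = FALSE)
  point_cloud(as.matrix(df[, need]),
              intensity = if ("intensity" %in% names(df)) df$intensity,
              cell = if ("cell" %in% names(df)) df$cell,
              frame = frame)
}

#' @rdname read_point_cloud
#' @param cloud a [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  df <- data.frame(cell = cloud$cell,
                   x = fmt17(cloud$points[, 1]),
                   y = fmt17(cloud$points[, 2]),
                   z = fmt17(cloud$points[, 3]),
                   stringsAsFactors = FALSE)
  if (!is.null(cloud$intensity)) df$intensity <- fmt17(cloud$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' One annotator's labelling of one worm: a map from cell index to neuron
#' label. Cells the annotator could not identify carry `NA`.
#'
#' @param worm worm/dataset identifier.
#' @param annotator annotator identifier.
#' @param cells vector of cell indices (unique within the set).
#' @param labels character vector of neuron labels (`NA` = unknown).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(worm, annotator, cells, labels) {
  if (anyDuplicated(cells))
    stop("cell indices must be unique within one annotation", call. = FALSE)
  if (length(cells) != length(labels))
    stop("cells and labels must have equal length", call. = FALSE)
  structure(list(worm = worm, annotator = annotator,
                 cells = cells, labels = as.character(labels)),
            class = "annotation_set")
}

#' Read / write annotation sets as CSV
#'
#' Format: header `worm,annotator,cell,label`; one file may hold several
#' annotators and worms (split on read).
#'
#' @param path CSV path.
#' @return `read_annotations`: a list of [annotation_set()] objects, one per
#'   (worm, annotator) pair, in file order.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  need <- c("worm", "annotator", "cell", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns worm, annotator, cell, label",
         call. = FALSE)
  df$label[df$label == ""] <- NA_character_
  key <- paste(df$worm, df$annotator, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g)
    annotation_set(g$worm[1], g$annotator[1], g$cell, g$label))
}

#' @rdname read_annotations
#' @param annotations a list of [annotation_set()] objects.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  df <- do.call(rbind, lapply(annotations, function(a)
    data.frame(worm = a$worm, annotator = a$annotator,
               cell = a$cells, label = a$labels, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a candidate-neuron list
#'
#' The identities a priori possible for a strain (e.g. the 37 neurons
#' expressing a reporter), optionally with left/right pair groupings used
#' for expression-side pooling.
#'
#' @param labels character vector of unique neuron labels, in display order.
#' @param pairs optional two-column matrix/data.frame of (left, right)
#'   label pairs; every entry must appear in `labels`.
#' @return An object of class `candidate_list`.
#' @export
candidate_list <- function(labels, pairs = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate candidate labels", call. = FALSE)
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
    if (!all(pairs %in% labels))
      stop("pair groupings reference labels absent from the candidate list",
           call. = FALSE)
  }
  structure(list(labels = labels, pairs = pairs), class = "candidate_list")
}

#' Read a candidate list from a plain-text file
#'
#' One label per line; a line `LEFT<TAB>RIGHT` (or `LEFT RIGHT`) declares a
#' bilateral pair and contributes both labels.
#'
#' @param path text file path.
#' @return A [candidate_list()].
#' @export
read_candidates <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  labels <- unlist(toks)
  pr <- do.call(rbind, Filter(function(t) length(t) == 2L, toks))
  candidate_list(labels, pairs = pr)
}

#' Read / write body axes as JSON
#'
#' Stores origin, the three unit vectors, and (when produced by the
#' symmetry search) the selected rotation angle and final symmetry score.
#' Round-trips are bit-exact.
#'
#' @param path JSON path.
#' @return `read_axes`: a [body_axes()].
#' @export
read_axes <- function(path) {
  j <- jsonlite::fromJSON(path)
  ax <- body_axes(origin = j$origin, ap = j$ap, lr = j$lr, dv = j$dv)
  ax$rotation_deg <- j$rotation_deg
  ax$symmetry_score <- j$symmetry_score
  ax
}

#' @rdname read_axes
#' @param axes a [body_axes()].
#' @export
write_axes <- function(axes, path) {
  stopifnot(inherits(axes, "body_axes"))
  jsonlite::write_json(
    list(origin = axes$origin, ap = axes$ap, lr = axes$lr, dv = axes$dv,
         rotation_deg = axes$rotation_deg,
         symmetry_score = axes$symmetry_score),
    path, digits = I(17), auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' Read / write a positional atlas as JSON
#'
#' The schema mirrors the in-memory atlas: `convention`, `labels`,
#' `counts`, `p_pa`, `p_lr`, `p_dv` (matrices over ordered label pairs),
#' `ang_mean` (labels x labels x 3), `ang_resultant`, and `provenance`.
#' Probabilities are validated to lie in [0, 1] on read; round-trips are
#' bit-exact.
#'
#' @param path JSON path.
#' @return `read_atlas`: a `worm_atlas` (see [build_atlas()]).
#' @export
read_atlas <- function(path) {
  j <- jsonlite::fromJSON(path)
  lab <- as.character(j$labels)
  n <- length(lab)
  shape <- function(m, what) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (!all(dim(m) == c(n, n)))
      stop("atlas ", what, " table is not ", n, "x", n, call. = FALSE)
    dimnames(m) <- list(lab, lab)
    m
  }
  for (p in c("p_pa", "p_lr", "p_dv")) {
    v <- as.matrix(j[[p]])
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("atlas ", p, " holds probabilities outside [0, 1]", call. = FALSE)
  }
  am <- array(as.numeric(unlist(j$ang_mean)), dim = c(n, n, 3),
              dimnames = list(lab, lab, c("ap", "lr", "dv")))
  atl <- structure(list(
    convention = j$convention,
    labels = lab,
    counts = shape(j$counts, "counts"),
    p_pa = shape(j$p_pa, "p_pa"),
    p_lr = shape(j$p_lr, "p_lr"),
    p_dv = shape(j$p_dv, "p_dv"),
    ang_mean = am,
    ang_resultant = shape(j$ang_resultant, "ang_resultant"),
    provenance = list(
      n_datasets = as.numeric(j$provenance$n_datasets),
      annotators = as.character(unlist(j$provenance$annotators)))),
    class = "worm_atlas")
  validate_atlas(atl)
  atl
}

#' @rdname read_atlas
#' @param atlas a `worm_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "worm_atlas"))
  jsonlite::write_json(
    list(convention = atlas$convention, labels = atlas$labels,
         counts = atlas$counts, p_pa = atlas$p_pa, p_lr = atlas$p_lr,
         p_dv = atlas$p_dv, ang_mean = atlas$ang_mean,
         ang_resultant = atlas$ang_resultant,
         provenance = atlas$provenance),
    path, digits = I(17), auto_unbox = FALSE, null = "null", na = "null",
    matrix = "rowmajor")
  invisible(path)
}

#' Write ranked or single predictions as CSV
#'
#' Format: `cell,rank,label,frequency` (ranked mode) or
#' `cell,rank,label,score` with `rank = 1` (single mode).
#'
#' @param prediction a `ranked_prediction` or `crf_assignment`.
#' @param path CSV path.
#' @export
write_predictions <- function(prediction, path) {
  if (inherits(prediction, "crf_assignment")) {
    df <- data.frame(cell = prediction$cells, rank = 1L,
                     label = prediction$labels,
                     score = prediction$score, stringsAsFactors = FALSE)
  } else if (inherits(prediction, "ranked_prediction")) {
    df <- do.call(rbind, lapply(seq_along(prediction$cells), function(i) {
      r <- prediction$ranking[[i]]
      if (nrow(r) == 0) return(NULL)
      data.frame(cell = prediction$cells[i], rank = seq_len(nrow(r)),
                 label = r$label, frequency = r$frequency,
                 stringsAsFactors = FALSE)
    }))
  } else stop("unsupported prediction object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage_log <- function(...) {
  message(sprintf("[wormid] %s", sprintf(...)))
}
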