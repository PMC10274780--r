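# Reporter-expression quantification. Segmentation masks come from the
# nuclear mCherry channel; GFP is read from the same voxels. Intensities
# are summarized as the mean of the brightest voxels in the mask,
# normalized per animal (and channel) by the mean over all measured
# neurons, and grouped by body side because the side facing the
# objective is systematically brighter (scattering through tissue).

#' Mean of the brightest voxels in a segmentation mask
#'
#' @param volume a [worm_volume()].
#' @param mask voxel index matrix (rows of z, y, x, 1-based) as produced
#'   by [detect_cells()].
#' @param top_n how many of the brightest voxels to average (default
#'   100); if the mask is smaller, all voxels are averaged with a
#'   warning.
#' @return Raw intensity (scalar).
#' @export
extract_intensity <- function(volume, mask, top_n = 100L) {
  stopifnot(inherits(volume, "worm_volume"))
  mask <- matrix(mask, ncol = 3)
  if (nrow(mask) == 0L) stop("empty mask", call. = FALSE)
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  v <- volume$data[mask]
  if (length(v) < top_n) {
    warning("mask has ", length(v), " voxels (< top_n = ", top_n,
            "); averaging all of them")
    return(mean(v))
  }
  mean(sort(v, decreasing = TRUE)[seq_len(top_n)])
}

#' Per-cell intensities from both channels through shared masks
#'
#' Applies each mCherry-derived mask to the red and the green volume.
#' Cells whose GFP expression was judged absent during curation are
#' named in `exclude_gfp` and get `NA` in the GFP column (their mCherry
#' value is kept).
#'
#' @param red_volume,green_volume co-registered [worm_volume()]s on the
#'   same voxel grid.
#' @param masks named list of voxel index matrices (names = cell ids),
#'   or a list of `detected_cell` objects.
#' @param top_n passed to [extract_intensity()].
#' @param exclude_gfp cell ids with curated-absent GFP.
#' @return Data frame: `cell`, `mCherry`, `GFP`.
#' @export
cross_channel_intensity <- function(red_volume, green_volume, masks,
                                    top_n = 100L, exclude_gfp = NULL) {
  if (!identical(dim(red_volume$data), dim(green_volume$data)))
    stop("red and green volumes are on different voxel grids", call. = FALSE)
  if (length(masks) && inherits(masks[[1]], "detected_cell")) {
    nm <- seq_along(masks)
    masks <- stats::setNames(lapply(masks, `[[`, "mask"), nm)
  }
  ids <- names(masks)
  if (is.null(ids)) ids <- as.character(seq_along(masks))
  red <- vapply(masks, function(m)
    extract_intensity(red_volume, m, top_n), 0)
  green <- vapply(masks, function(m)
    extract_intensity(green_volume, m, top_n), 0)
  green[ids %in% as.character(exclude_gfp)] <- NA_real_
  data.frame(cell = ids, mCherry = unname(red), GFP = unname(green),
             stringsAsFactors = FALSE)
}

#' Build a long-format expression table
#'
#' @param animal animal id (scalar).
#' @param intensities data frame from [cross_channel_intensity()].
#' @param labels named character vector cell id -> neuron label (e.g.
#'   from a reviewed prediction).
#' @param lr named numeric vector cell id -> worm-frame LR coordinate.
#' @return Data frame: `animal`, `cell`, `label`, `lr`, `channel`, `raw`.
#' @export
expression_table <- function(animal, intensities, labels, lr) {
  rows <- lapply(c("mCherry", "GFP"), function(ch) {
    raw <- intensities[[ch]]
    keep <- !is.na(raw)
    data.frame(animal = animal, cell = intensities$cell[keep],
               label = unname(labels[intensities$cell[keep]]),
               lr = unname(lr[intensities$cell[keep]]),
               channel = ch, raw = raw[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize intensities per animal and channel
#'
#' Divides each raw intensity by the mean raw intensity over all measured
#' neurons of that animal and channel, so the per-animal, per-channel
#' mean of the normalized values is exactly 1 and animals with different
#' overall expression levels become comparable.
#'
#' @param table long-format expression data frame with columns `animal`,
#'   `channel`, `raw` (see [expression_table()]).
#' @return The table with a `normalized` column added.
#' @export
normalize_per_animal <- function(table) {
  stopifnot(all(c("animal", "channel", "raw") %in% names(table)))
  key <- interaction(table$animal, table$channel, drop = TRUE)
  mu <- tapply(table$raw, key, mean)
  if (any(mu == 0))
    stop("zero mean intensity for some animal/channel; cannot normalize",
         call. = FALSE)
  table$normalized <- table$raw / as.numeric(mu[key])
  table
}

#' Group measurements into brighter and dimmer body sides
#'
#' The body side facing the objective scatters less and reads brighter,
#' so left/right homologs are pooled under their pair name and tagged by
#' relative brightness rather than anatomical side. For each animal the
#' side (sign of the worm-frame LR coordinate) with the higher mean raw
#' intensity across paired neurons (mCherry channel when present) is
#' tagged `brighter`; exact ties break toward the positive-LR side.
#' Unpaired (midline) neurons keep their own side tag and their own
#' label.
#'
#' @param table expression data frame with `animal`, `label`, `lr`,
#'   `channel`, `raw` columns.
#' @param pairings two-column matrix/data.frame of (left, right) labels,
#'   or a [candidate_list()] with pairs.
#' @param side_override optional named vector animal -> `"pos"`/`"neg"`
#'   declaring the brighter side explicitly.
#' @return The table with `side` (`brighter`/`dimmer`) and `group`
#'   (pair name for pooled homologs, own label otherwise) columns.
#' @export
group_by_side <- function(table, pairings, side_override = NULL) {
  if (inherits(pairings, "candidate_list")) pairings <- pairings$pairs
  pairings <- as.matrix(pairings)
  pair_name <- paste(pairings[, 1], pairings[, 2], sep = "/")
  pair_of <- c(stats::setNames(pair_name, pairings[, 1]),
               stats::setNames(pair_name, pairings[, 2]))
  paired <- table$label %in% c(pairings[, 1], pairings[, 2])
  table$group <- ifelse(paired, unname(pair_of[table$label]), table$label)
  table$side <- NA_character_
  ref_channel <- if ("mCherry" %in% table$channel) "mCherry"
                 else table$channel[1]
  for (an in unique(table$animal)) {
    sel <- table$animal == an
    ref <- sel & table$channel == ref_channel & paired
    pos <- ref & table$lr > 0
    neg <- ref & table$lr < 0
    if (!any(neg) || !any(pos)) {
      if (!any(neg) && !any(pos))
        warning("animal ", an, ": no paired neurons; sides by LR sign only")
      else warning("animal ", an,
                   ": paired cells on one side only; all tagged brighter")
      bright_pos <- TRUE
    } else if (!is.null(side_override) && !is.null(side_override[[as.character(an)]])) {
      bright_pos <- side_override[[as.character(an)]] == "pos"
    } else {
      mp <- mean(table$raw[pos]); mn <- mean(table$raw[neg])
      bright_pos <- mp >= mn              # tie -> positive-LR side
      if (mp == mn)
        stage_log("group_by_side: animal %s side tie; positive LR tagged brighter",
                  format(an))
    }
    on_bright <- if (bright_pos) table$lr[sel] > 0 else table$lr[sel] < 0
    table$side[sel] <- ifelse(on_bright, "brighter", "dimmer")
  }
  table
}

#' Correlation between normalized GFP and mCherry intensities
#'
#' Pearson correlation across cells measured in both channels; a
#' reporting utility for checking co-expression linearity.
#'
#' @param table normalized expression table ([normalize_per_animal()]).
#' @return List with `r`, `n`.
#' @export
channel_correlation <- function(table) {
  stopifnot("normalized" %in% names(table))
  wide <- merge(
    table[table$channel == "mCherry", c("animal", "cell", "normalized")],
    table[table$channel == "GFP", c("animal", "cell", "normalized")],
    by = c("animal", "cell"), suffixes = c("_mCherry", "_GFP"))
  list(r = stats::cor(wide$normalized_mCherry, wide$normalized_GFP),
       n = nrow(wide))
}
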