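## Nucleus detection from Hoechst, nucleus-seeded cell-body segmentation
## from Alexa488, border exclusion and region derivation. The pipeline is
## the standard reproducible recipe: Gaussian smooth -> Otsu threshold ->
## fill holes -> distance-transform watershed (to split touching nuclei) ->
## area filter; cell bodies by seeded propagation on the smoothed
## concanavalin-A channel.

## internal: flatfield on a plain matrix
flatfield_matrix <- function(px, reference = NULL) {
  m <- mean(px)
  if (m == 0) return(px)
  if (is.null(reference)) {
    ## illumination estimate: second-order polynomial surface fit to
    ## background-like pixels (below twice the median), so cells do not
    ## bias the surface and the smooth field inhomogeneity is removed
    ## essentially exactly
    H <- nrow(px); W <- ncol(px)
    yy <- rep(seq_len(H) / H - 0.5, W)
    xx <- rep(seq_len(W) / W - 0.5, each = H)
    bg <- which(px <= 2 * stats::median(px))
    if (length(bg) < 64) bg <- seq_along(px)
    X <- cbind(1, yy, xx, yy^2, xx^2, yy * xx)
    beta <- stats::lm.fit(X[bg, , drop = FALSE], as.vector(px)[bg])$coefficients
    beta[is.na(beta)] <- 0
    reference <- matrix(pmax(drop(X %*% beta), 1e-9), H, W)
  } else {
    if (any(reference <= 0))
      stop("illumination reference must be strictly positive")
    if (!all(dim(reference) == dim(px)))
      stop("illumination reference shape mismatch")
  }
  out <- px / reference
  out * (m / mean(out))
}

#' Flatfield-correct a field image
#'
#' Divides out the slowly varying illumination surface. If no reference is
#' supplied, the surface is estimated per field as a second-order
#' polynomial fitted to background-like pixels (foreground above twice the
#' median is excluded from the fit). The output is rescaled to preserve
#' the input mean; constant and all-zero images pass through unchanged.
#'
#' @param image A [field_image()].
#' @param reference Optional strictly positive illumination surface matrix
#'   of the same shape.
#' @return A corrected [field_image()].
#' @export
flatfield_correct <- function(image, reference = NULL) {
  stopifnot(inherits(image, "FieldImage"))
  out <- flatfield_matrix(image$pixels, reference)
  field_image(image$well, image$field_index, image$channel, pmax(out, 0),
              image$pixel_size_um)
}

#' Flatfield-correct every image of a plate bundle
#'
#' @param bundle A [plate_bundle()].
#' @return A corrected [plate_bundle()].
#' @export
flatfield_correct_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "PlateBundle"))
  for (key in names(bundle$images))
    for (ch in CP_CHANNELS)
      bundle$images[[key]][[ch]] <-
        pmax(flatfield_matrix(bundle$images[[key]][[ch]]), 0)
  bundle
}

## Deterministic relabeling 1..K ordered by first (column-major) pixel.
relabel_contiguous <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(list(labels = labels, map = integer(0)))
  first_px <- vapply(ids, function(i) which(labels == i)[1], numeric(1))
  ord <- ids[order(first_px)]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(ord)) out[labels == ord[k]] <- k
  list(labels = out, map = ord)
}

#' Detect nuclei in the Hoechst channel
#'
#' Gaussian smooth (sigma 2 px), Otsu threshold on log-compressed
#' intensity, hole filling, a
#' distance-transform watershed to split touching nuclei, an area filter,
#' and optional removal of objects touching any image edge. Labels in the
#' returned grid are contiguous 1..K, ordered deterministically.
#'
#' @param hoechst A [field_image()] with channel `Hoechst33342`.
#' @param min_area_px Minimum object area in pixels (default 50, tuned to
#'   reject debris while keeping shrunken dead cells at 20x-equivalent
#'   scale).
#' @param exclude_border Remove objects touching the image border.
#' @return Integer label matrix (class `nucleus_labels`), with attributes
#'   `n_border_excluded` and `n_small_excluded`.
#' @export
find_nuclei <- function(hoechst, min_area_px = 50L, exclude_border = TRUE) {
  stopifnot(inherits(hoechst, "FieldImage"))
  if (hoechst$channel != "Hoechst33342")
    stop("find_nuclei expects the Hoechst33342 channel, got ", hoechst$channel)
  px <- hoechst$pixels
  rng <- range(px)
  if (diff(rng) < 1e-12) {
    out <- matrix(0L, nrow(px), ncol(px))
    attr(out, "n_border_excluded") <- 0L
    attr(out, "n_small_excluded") <- 0L
    class(out) <- c("nucleus_labels", class(out))
    return(out)
  }
  norm <- (px - rng[1]) / diff(rng)
  sm <- EBImage::filter2(norm, gaussian_kernel(2), boundary = "replicate")
  sm <- pmin(pmax(sm, 0), 1)
  ## Otsu on log-compressed intensity: robust when very bright (apoptotic)
  ## nuclei coexist with dim ones and would otherwise pull the threshold
  ## above the dim population
  lg <- log1p(sm * 100) / log1p(100)
  thr <- EBImage::otsu(EBImage::Image(lg), range = c(0, 1))
  bw <- lg > thr
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  storage.mode(labels) <- "integer"
  ## area filter
  tab <- tabulate(labels[labels > 0])
  small <- which(tab > 0 & tab < min_area_px)
  if (length(small)) labels[labels %in% small] <- 0L
  n_small <- length(small)
  ## border exclusion
  n_border <- 0L
  if (exclude_border) {
    border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
    border_ids <- border_ids[border_ids > 0]
    if (length(border_ids)) labels[labels %in% border_ids] <- 0L
    n_border <- length(border_ids)
  }
  rl <- relabel_contiguous(labels)
  out <- rl$labels
  attr(out, "n_border_excluded") <- n_border
  attr(out, "n_small_excluded") <- n_small
  class(out) <- c("nucleus_labels", class(out))
  out
}

#' Segment cell bodies around detected nuclei
#'
#' Nucleus-seeded propagation (seeded watershed) on the smoothed Alexa488
#' (ER/cytoplasm) channel; foreground from automatic Otsu thresholding,
#' always including the nucleus pixels so a nucleus without surrounding
#' signal degenerates to cell = nucleus. Cell labels equal their nucleus
#' labels.
#'
#' @param conA A [field_image()] with channel `Alexa488`.
#' @param nuclei Nucleus label grid from [find_nuclei()].
#' @return Integer cell label matrix.
#' @export
find_cells <- function(conA, nuclei) {
  stopifnot(inherits(conA, "FieldImage"))
  if (conA$channel != "Alexa488")
    stop("find_cells expects the Alexa488 channel, got ", conA$channel)
  px <- conA$pixels
  if (!all(dim(px) == dim(nuclei)))
    stop("shape mismatch between Alexa488 grid and nucleus labels")
  nuc <- unclass(nuclei)
  attributes(nuc) <- list(dim = dim(nuc))
  storage.mode(nuc) <- "integer"
  if (max(nuc) == 0L) return(nuc)
  rng <- range(px)
  norm <- if (diff(rng) < 1e-12) matrix(0, nrow(px), ncol(px)) else
    (px - rng[1]) / diff(rng)
  sm <- pmin(pmax(EBImage::filter2(norm, gaussian_kernel(2), boundary = "replicate"), 0), 1)
  lg <- log1p(sm * 100) / log1p(100)
  thr <- EBImage::otsu(EBImage::Image(lg), range = c(0, 1))
  fg <- (lg > thr) | (nuc > 0L)
  cells <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(nuc),
                              mask = fg)
  cells <- EBImage::imageData(cells)
  storage.mode(cells) <- "integer"
  cells
}

#' Bundle a matched nucleus/cell segmentation
#'
#' Validates the segmentation invariants: every nucleus label has exactly
#' one matching cell label and nucleus pixels are contained in the matching
#' cell.
#'
#' @param well,field Well address and field index the masks belong to.
#' @param nucleus_mask,cell_mask Matched integer label grids.
#' @param pixel_size_um Pixel size in micrometres.
#' @param excluded_border_ids Count or ids of border-excluded objects
#'   (bookkeeping only).
#' @return An object of class `CellSegmentation`.
#' @export
cell_segmentation <- function(well, field, nucleus_mask, cell_mask,
                              pixel_size_um = 1, excluded_border_ids = integer(0)) {
  nm <- unclass(nucleus_mask); attributes(nm) <- list(dim = dim(nucleus_mask))
  cm <- unclass(cell_mask); attributes(cm) <- list(dim = dim(cell_mask))
  storage.mode(nm) <- "integer"; storage.mode(cm) <- "integer"
  if (!all(dim(nm) == dim(cm))) stop("mask shape mismatch")
  nuc_ids <- sort(unique(nm[nm > 0]))
  cell_ids <- sort(unique(cm[cm > 0]))
  if (!identical(nuc_ids, cell_ids))
    stop("orphan labels: nuclei ", paste(setdiff(nuc_ids, cell_ids), collapse = ","),
         " / cells ", paste(setdiff(cell_ids, nuc_ids), collapse = ","))
  bad <- nm > 0 & nm != cm
  if (any(bad))
    stop("nucleus pixels outside their matching cell for label(s) ",
         paste(unique(nm[bad]), collapse = ","))
  structure(list(well = well, field = field, nucleus_mask = nm,
                 cell_mask = cm, cell_ids = nuc_ids,
                 excluded_border_ids = excluded_border_ids,
                 pixel_size_um = pixel_size_um),
            class = "CellSegmentation")
}

#' @export
print.CellSegmentation <- function(x, ...) {
  cat(sprintf("CellSegmentation %s f%02d: %d cell(s)\n", x$well, x$field,
              length(x$cell_ids)))
  invisible(x)
}

#' Segment one field of a plate bundle
#'
#' Runs [find_nuclei()] on the Hoechst channel and [find_cells()] on the
#' Alexa488 channel and returns the matched segmentation.
#'
#' @param bundle A [plate_bundle()] (already flatfield-corrected if
#'   desired).
#' @param well,field Well address and field index.
#' @inheritParams find_nuclei
#' @return A [cell_segmentation()].
#' @export
segment_field <- function(bundle, well, field, min_area_px = 50L,
                          exclude_border = TRUE) {
  hoechst <- get_field_image(bundle, well, field, "Hoechst33342")
  conA <- get_field_image(bundle, well, field, "Alexa488")
  nuclei <- find_nuclei(hoechst, min_area_px = min_area_px,
                        exclude_border = exclude_border)
  cells <- find_cells(conA, nuclei)
  cell_segmentation(well, field, nuclei, cells,
                    pixel_size_um = bundle$pixel_size_um,
                    excluded_border_ids = attr(nuclei, "n_border_excluded"))
}

#' Derive the three analysis regions per cell
#'
#' Per cell id, the pixel index sets of the `nucleus`, `cytoplasm`
#' (cell minus nucleus, possibly empty) and full `cell` regions. The set
#' identities cytoplasm = cell \ nucleus and cell = nucleus U cytoplasm
#' hold exactly.
#'
#' @param seg A [cell_segmentation()].
#' @return An object of class `RegionSet`: a named list (by cell id) of
#'   lists with integer linear-index vectors `nucleus`, `cytoplasm`,
#'   `cell`, plus attributes `mask_dim` and `pixel_size_um`.
#' @export
derive_regions <- function(seg) {
  stopifnot(inherits(seg, "CellSegmentation"))
  out <- list()
  for (id in seg$cell_ids) {
    cell_idx <- which(seg$cell_mask == id)
    nuc_idx <- which(seg$nucleus_mask == id)
    out[[as.character(id)]] <- list(nucleus = nuc_idx,
                                    cytoplasm = setdiff(cell_idx, nuc_idx),
                                    cell = cell_idx)
  }
  structure(out, mask_dim = dim(seg$cell_mask),
            pixel_size_um = seg$pixel_size_um, class = "RegionSet")
}

## Per-cell centroid/area summary (nucleus centroid for crops, cell
## centroid for context features).
seg_cell_summary <- function(seg) {
  H <- nrow(seg$cell_mask)
  rows <- lapply(seg$cell_ids, function(id) {
    nidx <- which(seg$nucleus_mask == id)
    cidx <- which(seg$cell_mask == id)
    nr <- (nidx - 1) %% H; nc <- (nidx - 1) %/% H
    cr <- (cidx - 1) %% H; cc <- (cidx - 1) %/% H
    data.frame(well = seg$well, field = seg$field, cell_id = id,
               cy = mean(nr), cx = mean(nc),
               cell_cy = mean(cr), cell_cx = mean(cc),
               nucleus_area_px = length(nidx), cell_area_px = length(cidx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
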