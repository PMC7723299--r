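# Label transforms: turn instance masks into the continuous training
# targets used by the distance-prediction network, plus the discrete
# boundary/border encodings they are compared against.

#' Neighbor-distance configuration
#'
#' Parameters of the neighbor-distance transform: the radius of the
#' grayscale closing that bridges small gaps between close cells, and the
#' exponent that steepens the decline of the map towards cell interiors.
#'
#' @param closing_radius structuring-element radius in pixels for the
#'   grayscale closing (disk in 2D, sphere in 3D). Default 2.
#' @param power positive integer exponent applied pixelwise after closing.
#'   Default 3 confines the neighbor signal to the outer cell area.
#' @return object of class `neighbor_distance_config`.
#' @export
neighbor_distance_config <- function(closing_radius = 2, power = 3) {
  if (closing_radius < 0) stop("closing_radius must be >= 0")
  if (power < 1) stop("power must be >= 1")
  structure(list(closing_radius = closing_radius, power = as.integer(power)),
            class = "neighbor_distance_config")
}

#' Cell-distance map
#'
#' For each cell independently (all other cells treated as background),
#' every cell pixel is assigned its Euclidean distance to the nearest
#' non-cell pixel, normalized by the maximum distance within that cell so
#' that values lie in \[0, 1\] and peak at 1 in the cell interior.
#' Background pixels are 0.
#'
#' @param labels integer matrix/array instance mask; 0 = background.
#' @return numeric array of the same shape, values in \[0, 1\].
#' @export
cell_distance <- function(labels) {
  labels <- as_label_array(labels)
  out <- array(0, dim(labels))
  d <- dim(labels)
  nd <- length(d)
  for (id in label_ids(labels)) {
    pix <- which(labels == id)
    # crop to the bounding box expanded by one pixel: the surrounding ring
    # contains only non-cell pixels, so the in-crop EDT is exact
    co <- arrayInd(pix, d)
    ranges <- lapply(seq_len(nd), function(a) {
      seq(max(1L, min(co[, a]) - 1L), min(d[a], max(co[, a]) + 1L))
    })
    sub <- do.call(`[`, c(list(labels), ranges, list(drop = FALSE)))
    dist <- distance_transform(sub == id)
    vals <- dist[sub == id]
    mx <- max(vals)
    dist <- dist / mx
    dist[sub != id] <- 0
    cur <- do.call(`[`, c(list(out), ranges, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), ranges, list(value = cur + dist)))
  }
  out
}

#' Neighbor-distance map
#'
#' For each cell independently: the selected cell and the background are
#' treated as foreground and all other cells as background, the Euclidean
#' distance transform of that binary image is restricted to the selected
#' cell, normalized to \[0, 1\] by its per-cell maximum and inverted. The
#' per-cell results are assembled into one map, grayscale-closed and raised
#' to a power. Cells with no other cell in the image get 0 everywhere;
#' normalization suppresses the signal for cells without close neighbors.
#'
#' @inheritParams cell_distance
#' @param cfg a [neighbor_distance_config()].
#' @return numeric array of the same shape, values in \[0, 1\].
#' @export
neighbor_distance <- function(labels, cfg = neighbor_distance_config()) {
  labels <- as_label_array(labels)
  stopifnot(inherits(cfg, "neighbor_distance_config"))
  out <- array(0, dim(labels))
  ids <- label_ids(labels)
  for (id in ids) {
    if (length(ids) < 2) break
    # selected cell and background become foreground; the zero set (the
    # EDT reference) is the pixels of the other cells
    fg <- labels == id | labels == 0L
    dist <- distance_transform(fg)
    cellpix <- labels == id
    vals <- dist[cellpix]
    mx <- max(vals)
    out[cellpix] <- 1 - vals / mx
  }
  if (cfg$closing_radius > 0) {
    offs <- se_offsets(cfg$closing_radius, length(dim(labels)), "disk")
    out <- gray_close(out, offs)
  }
  out[labels == 0] <- 0
  out^cfg$power
}

#' Boundary and border encodings
#'
#' `boundary` marks the pixels of each cell adjacent (8-connectivity in 2D,
#' 26 in 3D) to any pixel not belonging to that cell; `border` is the
#' subset adjacent to a *different* cell, i.e. touching interfaces only.
#' Out-of-frame pixels do not induce boundaries.
#'
#' @inheritParams cell_distance
#' @return list with logical arrays `boundary` and `border`
#'   (`border` is always a subset of `boundary`).
#' @export
boundary_and_border <- function(labels) {
  labels <- as_label_array(labels)
  d <- dim(labels)
  offs <- se_offsets(1, length(d), "box")
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  boundary <- array(FALSE, d)
  border <- array(FALSE, d)
  cell <- labels > 0
  for (i in seq_len(nrow(offs))) {
    nb <- shift_array(labels, offs[i, ], NA_integer_)
    differs <- cell & !is.na(nb) & nb != labels
    boundary <- boundary | differs
    border <- border | (differs & nb > 0)
  }
  list(boundary = boundary, border = border)
}

#' Perturb a single cell by erosion or dilation
#'
#' Emulates an annotation inconsistency: one cell mask is morphologically
#' eroded or dilated while every other cell stays untouched. A dilation may
#' only claim background pixels, never pixels of other cells.
#'
#' @inheritParams cell_distance
#' @param cell_id cell to perturb (must be present).
#' @param mode `"erode"` or `"dilate"`.
#' @param radius structuring-element radius (0 = identity).
#' @param shape structuring-element shape, `"disk"` or `"box"`.
#' @return perturbed label image.
#' @export
perturb_cell <- function(labels, cell_id, mode = c("erode", "dilate"),
                         radius = 1, shape = c("disk", "box")) {
  labels <- as_label_array(labels)
  mode <- match.arg(mode)
  shape <- match.arg(shape)
  mask <- labels == cell_id
  if (!any(mask)) stop("cell_id ", cell_id, " not present in label image")
  if (radius == 0) return(labels)
  offs <- se_offsets(radius, length(dim(labels)), shape)
  if (mode == "erode") {
    er <- binary_erode(mask, offs)
    if (!any(er)) stop("erosion would remove cell ", cell_id, " entirely")
    labels[mask] <- 0L
    labels[er] <- as.integer(cell_id)
  } else {
    claim <- binary_dilate(mask, offs) & labels == 0L
    labels[claim] <- as.integer(cell_id)
  }
  labels
}

#' Pixel fraction of a representation
#'
#' Ratio of foreground pixels to all pixels, in per mille. Binary maps
#' (values only 0/1) count nonzero pixels; continuous maps such as neighbor
#' distances count pixels strictly greater than `neighbor_threshold`.
#'
#' @param maps a single map or a list of maps sharing one shape.
#' @param neighbor_threshold threshold for continuous maps (default 0.5).
#' @return numeric vector of per-mille fractions, one per map.
#' @export
representation_pixel_fraction <- function(maps, neighbor_threshold = 0.5) {
  if (!is.list(maps)) maps <- list(maps)
  shp <- dim(maps[[1]])
  vapply(maps, function(m) {
    if (!identical(dim(m), shp)) stop("maps must share one shape")
    binary <- all(m %in% c(0, 1))
    n <- if (binary) sum(m != 0) else sum(m > neighbor_threshold)
    1000 * n / length(m)
  }, numeric(1))
}
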