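# Watershed post-processing: turn a pair of (predicted) distance maps into
# an instance segmentation. Pipeline: Gaussian smoothing of both maps, mask
# extraction by thresholding the smoothed cell distance, seed extraction by
# thresholding (cell - neighbor^e), seeded watershed flooding of the
# negated smoothed cell distance, and an optional re-splitting of merged
# objects in 3D.

#' Post-processing configuration
#'
#' @param rho_mask mask threshold applied (strictly) to the smoothed cell
#'   distance. Default 0.09.
#' @param rho_seed seed threshold applied (strictly) to the smoothed
#'   cell distance minus the powered smoothed neighbor distance.
#'   Default 0.5.
#' @param sigma per-axis Gaussian standard deviation used to smooth both
#'   maps before thresholding; order (row, col\[, plane\]). Defaults
#'   `c(1.5, 1.5)` in 2D and `c(1.5, 1.5, 0.5)` in 3D (weaker smoothing
#'   across planes for anisotropic stacks).
#' @param neighbor_exponent exponent applied to the smoothed neighbor
#'   distance in the seed criterion; 2 by default, can be raised for a
#'   steeper suppression or set to 1 to omit it.
#' @param min_seed_area seed components smaller than this many pixels are
#'   removed. Default 3.
#' @param split_volume_factor in 3D, objects larger than this factor times
#'   the mean object volume are candidates for re-splitting. Default 4/3.
#' @param split_step,split_cap increment and cap for the seed threshold
#'   while re-splitting merged 3D objects.
#' @return object of class `postprocess_config`.
#' @export
postprocess_config <- function(rho_mask = 0.09, rho_seed = 0.5,
                               sigma = NULL, neighbor_exponent = 2,
                               min_seed_area = 3,
                               split_volume_factor = 4 / 3,
                               split_step = 0.05, split_cap = 0.95) {
  stopifnot(rho_mask > 0, rho_mask < 1, rho_seed > 0, rho_seed < 1,
            min_seed_area >= 1)
  structure(list(rho_mask = rho_mask, rho_seed = rho_seed, sigma = sigma,
                 neighbor_exponent = neighbor_exponent,
                 min_seed_area = min_seed_area,
                 split_volume_factor = split_volume_factor,
                 split_step = split_step, split_cap = split_cap),
            class = "postprocess_config")
}

default_sigma <- function(ndim) {
  if (ndim >= 3) c(1.5, 1.5, 0.5) else c(1.5, 1.5)
}

#' Smooth a distance pair
#'
#' Gaussian smoothing of both maps (reflect boundary handling);
#' `sigma = 0` on an axis leaves that axis untouched.
#'
#' @param pair list with numeric arrays `cell` and `neighbor`.
#' @param sigma per-axis standard deviations.
#' @return smoothed pair.
#' @export
smooth_distances <- function(pair, sigma = NULL) {
  if (is.null(sigma)) sigma <- default_sigma(length(dim(pair$cell)))
  list(cell = gaussian_smooth(pair$cell, sigma),
       neighbor = gaussian_smooth(pair$neighbor, sigma))
}

#' Extract the region to flood
#'
#' @param cell_smoothed smoothed cell-distance map.
#' @param rho_mask threshold; pixels strictly greater are kept.
#' @return logical array.
#' @export
extract_mask <- function(cell_smoothed, rho_mask = 0.09) {
  cell_smoothed > rho_mask
}

#' Extract watershed seeds
#'
#' Thresholds the smoothed cell distance minus the powered smoothed
#' neighbor distance, labels connected components and removes components
#' smaller than `min_seed_area` pixels.
#'
#' @param pair_smoothed smoothed distance pair.
#' @param rho_seed strict threshold.
#' @param neighbor_exponent exponent on the neighbor map.
#' @param min_seed_area minimum component size in pixels.
#' @return integer seed label array.
#' @export
extract_seeds <- function(pair_smoothed, rho_seed = 0.5,
                          neighbor_exponent = 2, min_seed_area = 3) {
  crit <- pair_smoothed$cell - pair_smoothed$neighbor^neighbor_exponent
  seeds <- label_components(crit > rho_seed, "full")
  if (min_seed_area > 1 && any(seeds > 0)) {
    sz <- tabulate(seeds)
    drop <- which(sz < min_seed_area & sz > 0)
    if (length(drop)) seeds[seeds %in% drop] <- 0L
  }
  seeds
}

#' Seeded watershed assignment
#'
#' Floods the negated smoothed cell distance from the seeds, restricted to
#' the mask, with face connectivity (4 in 2D, 6 in 3D). Every mask pixel
#' reachable from a seed gets exactly one label; pixels outside the mask
#' are 0. Deterministic: ties are resolved by flooding order.
#'
#' @param mask logical array to flood.
#' @param seeds integer seed labels (clipped to the mask).
#' @param cell_smoothed smoothed cell-distance map (the topography).
#' @return integer label array.
#' @export
watershed_assign <- function(mask, seeds, cell_smoothed) {
  if (!any(seeds > 0 & mask)) {
    warning("no seeds inside mask; returning empty segmentation")
    return(array(0L, dim(mask)))
  }
  out <- cpp_watershed(as.numeric(cell_smoothed), as.integer(seeds),
                       as.logical(mask), as.integer(dim(mask)))
  dim(out) <- dim(mask)
  out
}

#' Re-split merged objects in a 3D segmentation
#'
#' Objects whose volume exceeds `split_volume_factor` times the mean object
#' volume are re-processed: the seed threshold is raised in fixed
#' increments within the object's region until at least two seeds appear
#' (or the cap is reached), then a local watershed re-splits the object.
#' Objects for which no second seed appears are kept unchanged.
#'
#' @param segmentation 3D integer label array.
#' @param pair_smoothed smoothed distance pair of matching shape.
#' @param cfg a [postprocess_config()].
#' @return relabeled segmentation.
#' @export
split_merged_3d <- function(segmentation, pair_smoothed,
                            cfg = postprocess_config()) {
  ids <- label_ids(segmentation)
  if (length(ids) < 1) return(segmentation)
  vols <- vapply(ids, function(i) sum(segmentation == i), numeric(1))
  big <- ids[vols > cfg$split_volume_factor * mean(vols)]
  next_id <- max(ids)
  for (id in big) {
    obj <- segmentation == id
    crit <- pair_smoothed$cell - pair_smoothed$neighbor^cfg$neighbor_exponent
    crit[!obj] <- -Inf
    rho <- cfg$rho_seed
    seeds <- NULL
    while (rho <= cfg$split_cap) {
      s <- label_components(crit > rho, "full")
      sz <- tabulate(s)
      keep <- which(sz >= cfg$min_seed_area)
      if (length(keep) >= 2) {
        s[!(s %in% keep)] <- 0L
        seeds <- s
        break
      }
      rho <- rho + cfg$split_step
    }
    if (is.null(seeds)) {
      message("object ", id, " exceeded the volume limit but produced no ",
              "second seed up to the threshold cap; kept unchanged")
      next
    }
    ws <- watershed_assign(obj, seeds, pair_smoothed$cell)
    parts <- label_ids(ws)
    remap <- integer(max(parts))
    remap[parts[1]] <- id
    for (p in parts[-1]) {
      next_id <- next_id + 1L
      remap[p] <- next_id
    }
    segmentation[obj] <- 0L
    nz <- ws > 0
    segmentation[nz] <- remap[ws[nz]]
  }
  segmentation
}

#' Segment frames from distance predictions
#'
#' Runs the full post-processing per frame: predict (or look up) the
#' distance pair, smooth, threshold mask and seeds, flood. 3D volumes are
#' predicted slice-wise, stacked, and post-processed in 3D with
#' anisotropic smoothing; optionally merged objects are re-split.
#'
#' @param images list of frames (2D matrices) or 3D arrays.
#' @param predict function `(image, index) -> list(cell=, neighbor=)`
#'   returning a distance pair at image resolution. For 3D input it is
#'   called per slice.
#' @param cfg a [postprocess_config()].
#' @param split_3d logical; run [split_merged_3d()] on 3D volumes.
#' @return list of integer label arrays, one per frame.
#' @export
segment_frames <- function(images, predict, cfg = postprocess_config(),
                           split_3d = FALSE) {
  lapply(seq_along(images), function(t) {
    img <- images[[t]]
    nd <- length(dim(img))
    if (nd == 2) {
      pair <- predict(img, t)
    } else {
      slices <- lapply(seq_len(dim(img)[3]),
                       function(z) predict(img[, , z], t))
      pair <- list(
        cell = array(unlist(lapply(slices, `[[`, "cell")), dim(img)),
        neighbor = array(unlist(lapply(slices, `[[`, "neighbor")), dim(img)))
    }
    sigma <- if (is.null(cfg$sigma)) default_sigma(nd) else cfg$sigma
    sm <- smooth_distances(pair, sigma)
    mask <- extract_mask(sm$cell, cfg$rho_mask)
    seeds <- extract_seeds(sm, cfg$rho_seed, cfg$neighbor_exponent,
                           cfg$min_seed_area)
    if (!any(seeds > 0 & mask)) return(array(0L, dim(img)))
    seg <- watershed_assign(mask, seeds, sm$cell)
    if (nd == 3 && split_3d) seg <- split_merged_3d(seg, sm, cfg)
    seg
  })
}
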