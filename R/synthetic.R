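# Synthetic microscopy generator: roundish/elliptical cells with a
# controllable fraction of touching pairs, intensity rendering with blur
# and additive noise, and image sequences with drift, random walk,
# divisions and transient occlusions. Provides ground-truth masks,
# lineages and "perfect" distance predictions so segmentation and tracking
# are testable without external data or trained weights.

#' Scene configuration for synthetic frames
#'
#' @param size image size `c(rows, cols)`.
#' @param n_cells integer range `c(min, max)` of cells per frame.
#' @param semi_major,semi_minor ranges of ellipse semi-axes in pixels.
#' @param touching_fraction target fraction of cells that touch another
#'   cell (8-adjacency). Cells are placed in adjacent pairs to reach it.
#' @param fg,bg mean foreground/background intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian blur applied to the rendered intensities.
#' @param margin minimum distance of cell centers from the frame edge.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(size = c(192, 192), n_cells = c(5, 25),
                         semi_major = c(6, 11), semi_minor = c(5, 8),
                         touching_fraction = 0.4, fg = 0.7, bg = 0.1,
                         noise_sd = 0.04, blur_sigma = 1, margin = 12) {
  stopifnot(all(semi_minor >= 1), touching_fraction >= 0,
            touching_fraction <= 1)
  structure(list(size = size, n_cells = n_cells, semi_major = semi_major,
                 semi_minor = semi_minor,
                 touching_fraction = touching_fraction, fg = fg, bg = bg,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 margin = margin),
            class = "scene_config")
}

#' Motion configuration for synthetic sequences
#'
#' @param n_frames number of frames.
#' @param drift global per-frame drift `c(drow, dcol)` in pixels.
#' @param walk_sd per-axis standard deviation of the per-cell random walk.
#' @param division_prob probability per cell per frame of a division.
#' @param division_events optional data.frame with columns `id`, `frame`:
#'   scheduled divisions (the cell divides so that daughters first appear
#'   at `frame`).
#' @param occlusion_events optional data.frame with columns `id`, `start`,
#'   `duration`: the cell is omitted from the label images for
#'   `start, ..., start + duration - 1` but keeps its identity.
#' @param size_ratio daughter/parent area ratio at division (per daughter).
#'   Default 0.4: post-mitotic daughter nuclei are smaller than the
#'   G2/M mother nucleus.
#' @return object of class `motion_config`.
#' @export
motion_config <- function(n_frames = 20, drift = c(1, 1), walk_sd = 0.7,
                          division_prob = 0, division_events = NULL,
                          occlusion_events = NULL, size_ratio = 0.4) {
  stopifnot(n_frames >= 1, division_prob >= 0, division_prob <= 1)
  if (!is.null(occlusion_events)) stopifnot(all(occlusion_events$duration >= 1))
  structure(list(n_frames = n_frames, drift = drift, walk_sd = walk_sd,
                 division_prob = division_prob,
                 division_events = division_events,
                 occlusion_events = occlusion_events,
                 size_ratio = size_ratio),
            class = "motion_config")
}

# Pixel set of an ellipse by analytic inequality on pixel centers.
ellipse_mask <- function(size, center, a, b, phi) {
  r <- matrix(seq_len(size[1]), size[1], size[2]) - center[1]
  c <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE) - center[2]
  u <- cos(phi) * r + sin(phi) * c
  v <- -sin(phi) * r + cos(phi) * c
  (u / a)^2 + (v / b)^2 <= 1
}

sample_cell_geometry <- function(cfg) {
  list(a = runif(1, cfg$semi_major[1], cfg$semi_major[2]),
       b = runif(1, cfg$semi_minor[1], cfg$semi_minor[2]),
       phi = runif(1, 0, pi))
}

# Place one cell adjacent (gap 0, no overlap) to an anchor cell by
# stepping inward along a random direction in half-pixel steps.
place_touching <- function(labels, anchor_mask, other_mask, geom, cfg) {
  d <- dim(labels)
  adj <- binary_dilate(anchor_mask, se_offsets(1, 2, "box"))
  co <- which(anchor_mask, arr.ind = TRUE)
  ctr <- colMeans(co)
  for (try in 1:25) {
    theta <- runif(1, 0, 2 * pi)
    dir <- c(cos(theta), sin(theta))
    far <- max(cfg$semi_major) * 2 + 4
    for (s in seq(far, 1, by = -0.5)) {
      cand_ctr <- ctr + s * dir
      if (any(cand_ctr < cfg$margin) || any(cand_ctr > d - cfg$margin)) next
      cand <- ellipse_mask(d, cand_ctr, geom$a, geom$b, geom$phi)
      if (!any(cand)) next
      if (any(cand & (anchor_mask | other_mask))) break  # overlap: too close
      if (any(cand & adj)) {
        # touching the anchor; must not touch any third cell
        adj_other <- binary_dilate(other_mask, se_offsets(1, 2, "box"))
        if (!any(cand & adj_other)) return(cand)
        break
      }
    }
  }
  NULL
}

place_separate <- function(labels, occupied_dil, geom, cfg) {
  d <- dim(labels)
  for (try in 1:60) {
    ctr <- c(runif(1, cfg$margin, d[1] - cfg$margin),
             runif(1, cfg$margin, d[2] - cfg$margin))
    cand <- ellipse_mask(d, ctr, geom$a, geom$b, geom$phi)
    if (any(cand) && !any(cand & occupied_dil)) return(cand)
  }
  NULL
}

#' Generate one synthetic frame
#'
#' Renders non-overlapping (but possibly touching) elliptical cells with
#' the configured intensities, blur and noise. Deterministic per seed.
#'
#' @param cfg a [scene_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `image` (numeric matrix) and `labels` (integer mask).
#' @export
generate_frame <- function(cfg = scene_config(), seed = NULL) {
  run <- function() {
    d <- cfg$size
    n <- if (cfg$n_cells[1] == cfg$n_cells[2]) cfg$n_cells[1] else
      sample(cfg$n_cells[1]:cfg$n_cells[2], 1)
    n_pairs <- round(cfg$touching_fraction * n / 2)
    labels <- array(0L, d)
    se <- se_offsets(1, 2, "box")
    id <- 0L
    placed <- 0L
    while (placed < n) {
      occupied <- labels > 0
      occupied_dil <- binary_dilate(binary_dilate(occupied, se), se)
      geom <- sample_cell_geometry(cfg)
      if (id < 2L * n_pairs && placed + 1L < n) {
        m1 <- place_separate(labels, occupied_dil, geom, cfg)
        if (is.null(m1)) stop("could not place cells; reduce density")
        id <- id + 1L
        labels[m1] <- id
        geom2 <- sample_cell_geometry(cfg)
        other <- labels > 0 & labels != id
        m2 <- place_touching(labels, m1, other, geom2, cfg)
        id <- id + 1L
        if (is.null(m2)) { # fall back to a separate placement
          occupied_dil <- binary_dilate(binary_dilate(labels > 0, se), se)
          m2 <- place_separate(labels, occupied_dil, geom2, cfg)
          if (is.null(m2)) stop("could not place cells; reduce density")
        }
        labels[m2 & labels == 0L] <- id
        placed <- placed + 2L
      } else {
        m <- place_separate(labels, occupied_dil, geom, cfg)
        if (is.null(m)) stop("could not place cells; reduce density")
        id <- id + 1L
        labels[m] <- id
        placed <- placed + 1L
      }
    }
    list(image = render_image(labels, cfg), labels = labels)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

render_image <- function(labels, cfg) {
  img <- array(cfg$bg, dim(labels))
  for (id in label_ids(labels)) {
    img[labels == id] <- cfg$fg * runif(1, 0.9, 1.1)
  }
  if (cfg$blur_sigma > 0) img <- gaussian_smooth(img, cfg$blur_sigma)
  img + rnorm(length(img), sd = cfg$noise_sd) * 1
}

#' Generate a synthetic image sequence with ground-truth lineage
#'
#' Cells from an initial frame move with global drift plus a per-cell
#' random walk; scheduled (or random) divisions replace a parent by two
#' adjacent daughters; occluded cells are omitted from the label images
#' for the event duration but keep their identity in the ground-truth
#' lineage. Cells pushed out of the frame end their track.
#'
#' @param scene a [scene_config()].
#' @param motion a [motion_config()].
#' @param seed integer seed.
#' @return list with `images`, `labels` (lists of frames) and `lineage`,
#'   a data.frame with columns `L` (label), `B`/`E` (0-based first/last
#'   frame) and `P` (parent label, 0 = none).
#' @export
generate_sequence <- function(scene = scene_config(),
                              motion = motion_config(), seed = NULL) {
  run <- function() {
    first <- generate_frame(scene)
    d <- scene$size
    ids <- label_ids(first$labels)
    cells <- lapply(ids, function(i) {
      co <- which(first$labels == i, arr.ind = TRUE)
      ctr <- colMeans(co)
      area <- nrow(co)
      ab <- sqrt(area / pi)
      list(id = i, center = ctr, a = ab * 1.15, b = ab / 1.15,
           phi = runif(1, 0, pi), alive = TRUE, birth = 1L, death = NA_integer_,
           parent = 0L)
    })
    names(cells) <- as.character(ids)
    occl <- motion$occlusion_events
    div_ev <- motion$division_events
    images <- vector("list", motion$n_frames)
    lab_frames <- vector("list", motion$n_frames)
    lab_frames[[1]] <- render_cells(cells, d, occl, 1L)
    images[[1]] <- render_image(lab_frames[[1]]$vis, scene)
    # frame 1 re-rendered from ellipse state so all frames share geometry
    max_id <- max(ids)
    for (t in 2:motion$n_frames) {
      for (nm in names(cells)) {
        cl <- cells[[nm]]
        if (!cl$alive) next
        cl$center <- cl$center + motion$drift + rnorm(2, sd = motion$walk_sd)
        cells[[nm]] <- cl
      }
      # divisions scheduled for this frame, then random ones
      due <- character(0)
      if (!is.null(div_ev)) {
        due <- as.character(div_ev$id[div_ev$frame == t])
      }
      for (nm in names(cells)) {
        cl <- cells[[nm]]
        if (!cl$alive || nm %in% due) next
        if (motion$division_prob > 0 && runif(1) < motion$division_prob) {
          due <- c(due, nm)
        }
      }
      for (nm in due) {
        cl <- cells[[nm]]
        if (is.null(cl) || !cl$alive) next
        cl$alive <- FALSE
        cl$death <- t - 1L
        cells[[nm]] <- cl
        theta <- runif(1, 0, pi)
        dir <- c(cos(theta), sin(theta))
        sc <- sqrt(motion$size_ratio)
        # daughters separate symmetrically along the division axis and
        # just touch: offset by the daughter radius along that axis
        off <- ellipse_radius_along(cl$a * sc, cl$b * sc, cl$phi, dir) + 0.2
        for (s in c(-1, 1)) {
          max_id <- max_id + 1L
          daughter <- list(id = max_id, center = cl$center + s * off * dir,
                           a = cl$a * sc, b = cl$b * sc, phi = cl$phi,
                           alive = TRUE, birth = t, death = NA_integer_,
                           parent = cl$id)
          cells[[as.character(max_id)]] <- daughter
        }
      }
      cells <- relax_cells(cells, t)
      fr <- render_cells(cells, d, occl, t)
      # cells that vanished from the frame (not by occlusion) end here
      for (nm in names(cells)) {
        cl <- cells[[nm]]
        if (cl$alive && !(cl$id %in% fr$present) && !is_occluded(occl, cl$id, t)) {
          cl$alive <- FALSE
          cl$death <- t - 1L
          cells[[nm]] <- cl
        }
      }
      lab_frames[[t]] <- fr
      images[[t]] <- render_image(fr$vis, scene)
    }
    lineage <- do.call(rbind, lapply(cells, function(cl) {
      last <- if (is.na(cl$death)) motion$n_frames else cl$death
      data.frame(L = cl$id, B = cl$birth - 1L, E = last - 1L, P = cl$parent)
    }))
    lineage <- lineage[order(lineage$L), , drop = FALSE]
    rownames(lineage) <- NULL
    list(images = images, labels = lapply(lab_frames, `[[`, "vis"),
         lineage = lineage)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Radius of an ellipse (semi-axes a >= b, orientation phi) along the
# direction of unit vector v.
ellipse_radius_along <- function(a, b, phi, v) {
  delta <- atan2(v[2], v[1]) - phi
  a * b / sqrt((b * cos(delta))^2 + (a * sin(delta))^2)
}

# Overlap relaxation: cells behave as slightly compressible ellipses and
# push each other apart instead of interpenetrating; the residual slight
# overlap renders as a touching interface.
relax_cells <- function(cells, t) {
  nms <- names(cells)[vapply(cells, function(cl) cl$alive && cl$birth <= t,
                             logical(1))]
  if (length(nms) < 2) return(cells)
  for (iter in 1:6) {
    moved <- FALSE
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq(i + 1, length(nms))) {
        ci <- cells[[nms[i]]]
        cj <- cells[[nms[j]]]
        v <- cj$center - ci$center
        dist <- sqrt(sum(v^2))
        u <- if (dist < 1e-6) c(1, 0) else v / dist
        ri <- ellipse_radius_along(ci$a, ci$b, ci$phi, u)
        rj <- ellipse_radius_along(cj$a, cj$b, cj$phi, u)
        target <- 0.97 * (ri + rj)
        if (dist < target) {
          push <- (target - dist) / 2
          ci$center <- ci$center - push * u
          cj$center <- cj$center + push * u
          cells[[nms[i]]] <- ci
          cells[[nms[j]]] <- cj
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  cells
}

is_occluded <- function(occl, id, t) {
  if (is.null(occl)) return(FALSE)
  any(occl$id == id & t >= occl$start & t < occl$start + occl$duration)
}

# Render the current cell states into a label frame. Earlier ids win
# conflicting pixels, which yields touching interfaces rather than
# overlaps. Returns visible labels and the set of ids with pixels.
render_cells <- function(cells, d, occl, t) {
  vis <- array(0L, d)
  present <- integer(0)
  ord <- order(vapply(cells, `[[`, numeric(1), "id"))
  for (cl in cells[ord]) {
    if (!cl$alive || cl$birth > t) next
    m <- ellipse_mask(d, cl$center, cl$a, cl$b, cl$phi)
    m <- m & vis == 0L
    if (!any(m)) next
    present <- c(present, cl$id)
    if (!is_occluded(occl, cl$id, t)) vis[m] <- cl$id
  }
  list(vis = vis, present = present)
}

#' Perfect distance predictions from ground truth
#'
#' Computes exactly [cell_distance()] and [neighbor_distance()] for a label
#' image, optionally perturbed with Gaussian noise; stands in for a trained
#' network in segmentation and tracking tests.
#'
#' @param labels integer label image.
#' @param ncfg a [neighbor_distance_config()].
#' @param noise_sd Gaussian noise added to both maps (0 = exact).
#' @return list with `cell` and `neighbor` maps.
#' @export
perfect_predictions <- function(labels, ncfg = neighbor_distance_config(),
                                noise_sd = 0) {
  pair <- list(cell = cell_distance(labels),
               neighbor = neighbor_distance(labels, ncfg))
  if (noise_sd > 0) {
    pair$cell <- pair$cell + rnorm(length(pair$cell), sd = noise_sd)
    pair$neighbor <- pair$neighbor + rnorm(length(pair$neighbor), sd = noise_sd)
  }
  pair
}

#' Predictor stub backed by ground-truth labels
#'
#' Returns a function with the `predict(image, index)` signature of
#' [segment_frames()] that ignores the image and returns perfect distance
#' predictions for the stored ground-truth frame.
#'
#' @param gt_labels list of ground-truth label frames (or a single one).
#' @inheritParams perfect_predictions
#' @return predictor function.
#' @export
make_perfect_predictor <- function(gt_labels,
                                   ncfg = neighbor_distance_config(),
                                   noise_sd = 0) {
  if (!is.list(gt_labels)) gt_labels <- list(gt_labels)
  cache <- vector("list", length(gt_labels))
  function(image, index = 1) {
    if (is.null(cache[[index]])) {
      cache[[index]] <<- perfect_predictions(gt_labels[[index]], ncfg,
                                             noise_sd)
    }
    cache[[index]]
  }
}
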