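# Graph-based tracking: objects segmented per frame are linked forward in
# time. Each active track carries a rectangular ROI; a phase correlation
# between the image crops at t and t+1 estimates the object movement, and
# an exact coupled minimum-cost-flow matching decides per step between
# match, disappearance and division, with new tracks for unmatched
# objects. Tracks without a mask for up to delta_t frames stay active and
# can be re-linked across the gap.

#' Tracker configuration
#'
#' @param delta_t maximum number of frames a track may lack a mask and
#'   still be re-linked. Default 3.
#' @param alpha minimum daughter size ratio (smaller/larger) for a
#'   division. Default 0.5.
#' @param beta maximum combined daughter size relative to the parent.
#'   Default 1.2.
#' @param gamma maximum daughter separation in pixels; `NULL` uses the
#'   rule `2 * V_last^(1/D)` with `D` the image dimensionality.
#' @param roi_extent per-axis ROI size in pixels; scalar or vector.
#'   Default 150 (2D); use e.g. `c(100, 100, 100)` for 3D.
#' @param appearance_cost cost of starting a new track (0: spurious
#'   tracks are filtered in post-processing).
#' @param disappearance_cost `NULL` uses the rule "longest ROI edge".
#' @param rho_factor the infeasible-split cost is `rho_factor` times the
#'   disappearance cost. Default 10.
#' @return object of class `tracker_config`.
#' @export
tracker_config <- function(delta_t = 3, alpha = 0.5, beta = 1.2,
                           gamma = NULL, roi_extent = 150,
                           appearance_cost = 0, disappearance_cost = NULL,
                           rho_factor = 10) {
  stopifnot(delta_t >= 0, alpha > 0, alpha <= 1, beta > 0,
            all(roi_extent > 0))
  structure(list(delta_t = delta_t, alpha = alpha, beta = beta,
                 gamma = gamma, roi_extent = roi_extent,
                 appearance_cost = appearance_cost,
                 disappearance_cost = disappearance_cost,
                 rho_factor = rho_factor),
            class = "tracker_config")
}

cfg_roi <- function(cfg, ndim) rep_len(cfg$roi_extent, ndim)

cfg_disappearance <- function(cfg, ndim) {
  if (!is.null(cfg$disappearance_cost)) cfg$disappearance_cost
  else max(cfg_roi(cfg, ndim))
}

cfg_gamma <- function(cfg, v_last, ndim) {
  if (!is.null(cfg$gamma)) cfg$gamma else 2 * v_last^(1 / ndim)
}

#' Summarize segmented objects of one frame
#'
#' Position is the per-axis median of the object's pixel coordinates
#' (consistent with ROI initialization); size is the pixel count.
#'
#' @param labels integer label image.
#' @return list of objects with `id`, `size`, `pos`, `coords`.
#' @export
object_stats <- function(labels) {
  labels <- as_label_array(labels)
  d <- dim(labels)
  lapply(label_ids(labels), function(id) {
    co <- arrayInd(which(labels == id), d)
    list(id = id, size = nrow(co), pos = apply(co, 2, median), coords = co)
  })
}

roi_ranges <- function(center, extent, d) {
  lapply(seq_along(d), function(a) {
    lo <- max(1L, as.integer(round(center[a] - extent[a] / 2)))
    hi <- min(d[a], as.integer(round(center[a] + extent[a] / 2)))
    lo:hi
  })
}

in_roi <- function(coords, ranges) {
  ok <- rep(TRUE, nrow(coords))
  for (a in seq_along(ranges)) {
    ok <- ok & coords[, a] >= ranges[[a]][1] &
      coords[, a] <= ranges[[a]][length(ranges[[a]])]
  }
  any(ok)
}

#' Initialize tracks from the first frame
#'
#' One track per segmented object (or per selected id), with the ROI
#' centered at the per-axis median position of the object's pixels.
#'
#' @param first_frame integer label image.
#' @param cfg a [tracker_config()].
#' @param selected_ids optional subset of object ids to track.
#' @return internal track-state list.
#' @export
initialize_tracks <- function(first_frame, cfg = tracker_config(),
                              selected_ids = NULL) {
  objs <- object_stats(first_frame)
  ids <- vapply(objs, `[[`, numeric(1), "id")
  if (!is.null(selected_ids)) {
    missing <- setdiff(selected_ids, ids)
    if (length(missing)) stop("selected ids not present: ",
                              paste(missing, collapse = ", "))
    objs <- objs[ids %in% selected_ids]
  }
  tracks <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    list(id = i, parent = 0L, frames = 1L,
         pos = matrix(o$pos, 1), sizes = o$size, closed = FALSE,
         roi_center = o$pos, coords = list(o$coords))
  })
  tracks
}

#' Estimate the shift between two image crops by phase correlation
#'
#' Returns the integer displacement `d` maximizing the inverse-transformed
#' normalized cross-power spectrum, mapped to signed shifts (wrap-around:
#' shifts beyond half the patch size are negative). `d` is the movement of
#' the content from the first to the second crop.
#'
#' @param crop_t,crop_t1 numeric arrays of equal shape.
#' @return integer displacement vector.
#' @export
estimate_shift <- function(crop_t, crop_t1) {
  if (!identical(dim(crop_t), dim(crop_t1))) stop("crop shapes must match")
  d <- dim(crop_t)
  if (max(crop_t) == min(crop_t) || max(crop_t1) == min(crop_t1)) {
    warning("degenerate (constant) patch; returning zero shift")
    return(integer(length(d)))
  }
  f1 <- fft(crop_t)
  f2 <- fft(crop_t1)
  r <- Conj(f1) * f2
  r <- r / pmax(Mod(r), 1e-12)
  corr <- Re(fft(r, inverse = TRUE))
  peak <- arrayInd(which.max(corr), d) - 1L
  shift <- as.integer(peak)
  wrap <- shift > d / 2
  shift[wrap] <- shift[wrap] - d[wrap]
  shift
}

#' Matching cost between a track and a candidate object
#'
#' Euclidean distance between the predicted position (last known position
#' plus estimated shift) and the candidate centroid.
#'
#' @param pos last known track position.
#' @param shift estimated displacement.
#' @param candidate_pos candidate object position.
#' @return non-negative cost.
#' @export
matching_cost <- function(pos, shift, candidate_pos) {
  sqrt(sum((pos + shift - candidate_pos)^2))
}

#' Split (division) cost for a candidate daughter pair
#'
#' The split condition admits a division only if the daughters are of
#' similar size (`V_n / V_k > alpha` after sorting so `V_k >= V_n`), their
#' combined size is similar to the parent (`(V_n + V_k) / V_last < beta`),
#' and they are close (`||p_n - p_k|| < gamma`). If admitted, the cost is
#' the distance from the predicted position to the daughters' midpoint;
#' otherwise the prohibitive cost `rho = rho_factor * disappearance cost`.
#'
#' @param pos,shift last known position and estimated displacement of the
#'   track.
#' @param v_last size of the track's last assigned mask.
#' @param pos_n,size_n,pos_k,size_k candidate daughter positions/sizes.
#' @param cfg a [tracker_config()].
#' @param ndim image dimensionality.
#' @return cost.
#' @export
split_cost <- function(pos, shift, v_last, pos_n, size_n, pos_k, size_k,
                       cfg = tracker_config(), ndim = length(pos)) {
  if (size_n > size_k) {  # sort so size_k >= size_n
    tmp <- pos_n; pos_n <- pos_k; pos_k <- tmp
    tmp <- size_n; size_n <- size_k; size_k <- tmp
  }
  rho <- cfg$rho_factor * cfg_disappearance(cfg, ndim)
  sep <- sqrt(sum((pos_n - pos_k)^2))
  ok <- (size_n / size_k > cfg$alpha) &&
    ((size_n + size_k) / v_last < cfg$beta) &&
    (sep < cfg_gamma(cfg, v_last, ndim))
  if (!ok) return(rho)
  mid <- (pos_n + pos_k) / 2
  sqrt(sum((pos + shift - mid)^2))
}

#' Build the matching graph for one tracking step
#'
#' For every active track: match edges to the candidate objects whose
#' pixels overlap its ROI (cost [matching_cost()]), a disappearance edge
#' (cost = longest ROI edge), and one split node per unordered candidate
#' pair (cost [split_cost()]). Every object additionally has an appearance
#' edge of cost 0. There are no merge nodes.
#'
#' @param tracks list of active track states.
#' @param objects object summaries of frame t+1 (see [object_stats()]).
#' @param shifts list/matrix of per-track estimated displacements.
#' @param cfg a [tracker_config()].
#' @param d image dimensions.
#' @return object of class `match_graph`.
#' @export
build_match_graph <- function(tracks, objects, shifts,
                              cfg = tracker_config(), d) {
  ndim <- length(d)
  extent <- cfg_roi(cfg, ndim)
  dis_cost <- cfg_disappearance(cfg, ndim)
  gtracks <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    sh <- shifts[[i]]
    ranges <- roi_ranges(tr$roi_center, extent, d)
    cand <- which(vapply(objects, function(o) in_roi(o$coords, ranges),
                         logical(1)))
    pos <- tr$pos[nrow(tr$pos), ]
    v_last <- tr$sizes[length(tr$sizes)]
    mcost <- vapply(cand, function(j)
      matching_cost(pos, sh, objects[[j]]$pos), numeric(1))
    splits <- NULL
    if (length(cand) >= 2) {
      prs <- utils::combn(cand, 2)
      splits <- data.frame(n = prs[1, ], k = prs[2, ])
      splits$cost <- vapply(seq_len(nrow(splits)), function(r) {
        on <- objects[[splits$n[r]]]
        ok <- objects[[splits$k[r]]]
        split_cost(pos, sh, v_last, on$pos, on$size, ok$pos, ok$size,
                   cfg, ndim)
      }, numeric(1))
    }
    list(track_index = i, candidates = cand, match_cost = mcost,
         disappearance_cost = dis_cost, splits = splits)
  })
  structure(list(tracks = gtracks, n_objects = length(objects),
                 appearance_cost = cfg$appearance_cost),
            class = "match_graph")
}

#' Solve the matching problem exactly
#'
#' Finds the minimum-total-cost assignment in which every track takes
#' exactly one decision (match one object, disappear, or split into an
#' object pair), every object is used by at most one decision, and
#' unused objects appear as new (appearance cost each). Exact depth-first
#' branch-and-bound; among equal-cost optima the lexicographically first
#' decision sequence (tracks in order, decisions sorted by cost then
#' type then object ids) is returned, deterministically.
#'
#' @param graph a `match_graph` from [build_match_graph()].
#' @return list with `decisions` (one per track: `type` in
#'   `"match"`/`"disappear"`/`"split"`, `objects`, `cost`), `new_objects`
#'   (indices assigned to the appearance node), and `total_cost`.
#' @export
solve_matching <- function(graph) {
  nt <- length(graph$tracks)
  nobj <- graph$n_objects
  opts <- lapply(graph$tracks, function(g) {
    dec <- list(list(type = "disappear", objects = integer(0),
                     cost = g$disappearance_cost))
    for (ci in seq_along(g$candidates)) {
      dec[[length(dec) + 1]] <- list(type = "match",
                                     objects = g$candidates[ci],
                                     cost = g$match_cost[ci])
    }
    if (!is.null(g$splits)) {
      for (r in seq_len(nrow(g$splits))) {
        dec[[length(dec) + 1]] <- list(
          type = "split", objects = c(g$splits$n[r], g$splits$k[r]),
          cost = g$splits$cost[r])
      }
    }
    typerank <- c(match = 1, split = 2, disappear = 3)
    key1 <- vapply(dec, `[[`, numeric(1), "cost")
    key2 <- typerank[vapply(dec, `[[`, character(1), "type")]
    key3 <- vapply(dec, function(x)
      sum(x$objects * c(1, 1e-4)[seq_along(x$objects)]), numeric(1))
    dec[order(key1, key2, key3)]
  })
  min_costs <- vapply(opts, function(d)
    min(vapply(d, `[[`, numeric(1), "cost")), numeric(1))
  suffix_min <- rev(cumsum(rev(c(min_costs, 0))))
  # every unused object costs one appearance; appearance cost is constant
  # per object so only track decisions enter the optimization
  best <- list(cost = Inf, decisions = NULL)
  used <- logical(nobj)
  current <- vector("list", nt)
  recurse <- function(i, acc) {
    if (acc + suffix_min[i] >= best$cost) return()
    if (i > nt) {
      best <<- list(cost = acc, decisions = current)
      return()
    }
    for (dec in opts[[i]]) {
      if (any(used[dec$objects])) next
      used[dec$objects] <<- TRUE
      current[[i]] <<- dec
      recurse(i + 1, acc + dec$cost)
      used[dec$objects] <<- FALSE
    }
  }
  recurse(1, 0)
  taken <- unlist(lapply(best$decisions, `[[`, "objects"))
  new_objects <- setdiff(seq_len(nobj), taken)
  list(decisions = best$decisions, new_objects = new_objects,
       total_cost = best$cost + length(new_objects) * graph$appearance_cost)
}

crop_at <- function(img, ranges) {
  do.call(`[`, c(list(img), ranges, list(drop = FALSE)))
}

#' Track a segmented image sequence
#'
#' Forward pass over the frames: per step the ROIs are updated with
#' phase-correlation shift estimates from the raw images, the matching
#' graph is built and solved, and the assignments are applied (a match
#' extends the track, a split closes the parent and opens two daughters
#' with parent links, a disappearing track stays active for up to
#' `delta_t` frames). Unmatched objects start new tracks unless
#' `selected_ids` restricts tracking to chosen first-frame objects.
#'
#' @param label_frames list of integer label images (the segmentation).
#' @param images optional list of raw image frames for movement
#'   estimation; `NULL` uses zero shifts.
#' @param cfg a [tracker_config()].
#' @param selected_ids optional first-frame object ids to track.
#' @return object of class `cell_lineage`: per-track records, relabeled
#'   mask frames (values are track ids), and bookkeeping.
#' @export
track_sequence <- function(label_frames, images = NULL,
                           cfg = tracker_config(), selected_ids = NULL) {
  nT <- length(label_frames)
  d <- dim(label_frames[[1]])
  for (f in label_frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
  }
  ndim <- length(d)
  extent <- cfg_roi(cfg, ndim)
  tracks <- initialize_tracks(label_frames[[1]], cfg, selected_ids)
  out <- vector("list", nT)
  out[[1]] <- array(0L, d)
  for (tr in tracks) out <- write_coords(out, 1L, tr$coords[[1]], tr$id, d)
  next_id <- length(tracks)
  if (nT > 1) for (t in seq_len(nT - 1)) {
    t_last <- vapply(tracks, function(tr) tr$frames[length(tr$frames)],
                     numeric(1))
    active <- which(!vapply(tracks, `[[`, logical(1), "closed") &
                      t_last >= t - cfg$delta_t & t_last <= t)
    objs <- object_stats(label_frames[[t + 1]])
    if (length(active)) {
      shifts <- lapply(active, function(i) {
        if (is.null(images)) return(integer(ndim))
        ranges <- roi_ranges(tracks[[i]]$roi_center, extent, d)
        estimate_shift(crop_at(images[[t]], ranges),
                       crop_at(images[[t + 1]], ranges))
      })
      graph <- build_match_graph(tracks[active], objs, shifts, cfg, d)
      sol <- solve_matching(graph)
      for (ai in seq_along(active)) {
        i <- active[ai]
        dec <- sol$decisions[[ai]]
        if (dec$type == "match") {
          o <- objs[[dec$objects]]
          tracks[[i]]$frames <- c(tracks[[i]]$frames, t + 1L)
          tracks[[i]]$pos <- rbind(tracks[[i]]$pos, o$pos)
          tracks[[i]]$sizes <- c(tracks[[i]]$sizes, o$size)
          tracks[[i]]$coords <- c(tracks[[i]]$coords, list(o$coords))
          tracks[[i]]$roi_center <- o$pos
          write_coords(out, t + 1L, o$coords, tracks[[i]]$id, d) -> out
        } else if (dec$type == "split") {
          tracks[[i]]$closed <- TRUE
          for (oi in dec$objects) {
            o <- objs[[oi]]
            next_id <- next_id + 1L
            tracks[[length(tracks) + 1]] <- list(
              id = next_id, parent = tracks[[i]]$id, frames = t + 1L,
              pos = matrix(o$pos, 1), sizes = o$size, closed = FALSE,
              roi_center = o$pos, coords = list(o$coords))
            write_coords(out, t + 1L, o$coords, next_id, d) -> out
          }
        } else {
          # disappearance: dead-reckon the ROI with the estimated shift
          tracks[[i]]$roi_center <- tracks[[i]]$roi_center + shifts[[ai]]
        }
      }
      unmatched <- sol$new_objects
    } else {
      unmatched <- seq_along(objs)
    }
    if (is.null(out[[t + 1]])) out[[t + 1]] <- array(0L, d)
    if (is.null(selected_ids)) {
      for (oi in unmatched) {
        o <- objs[[oi]]
        next_id <- next_id + 1L
        tracks[[length(tracks) + 1]] <- list(
          id = next_id, parent = 0L, frames = t + 1L,
          pos = matrix(o$pos, 1), sizes = o$size, closed = FALSE,
          roi_center = o$pos, coords = list(o$coords))
        write_coords(out, t + 1L, o$coords, next_id, d) -> out
      }
    }
  }
  structure(list(tracks = tracks, masks = out, delta_t = cfg$delta_t,
                 dim = d), class = "cell_lineage")
}

write_coords <- function(out, t, coords, id, d) {
  if (is.null(out[[t]])) out[[t]] <- array(0L, d)
  lin <- coords[, 1] + (coords[, 2] - 1) * d[1]
  if (length(d) == 3) lin <- lin + (coords[, 3] - 1) * d[1] * d[2]
  out[[t]][lin] <- id
  out
}

#' Lineage post-processing
#'
#' Fills re-linked gaps by replicating the last available mask at the
#' linearly interpolated (rounded) positions between the flanking real
#' masks, clipped to image bounds; then removes length-one tracks with
#' neither parent nor children.
#'
#' @param lineage a `cell_lineage` from [track_sequence()].
#' @return post-processed `cell_lineage`.
#' @export
postprocess_tracks <- function(lineage) {
  tracks <- lineage$tracks
  masks <- lineage$masks
  d <- lineage$dim
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    gaps <- which(diff(tr$frames) > 1)
    for (g in gaps) {
      f1 <- tr$frames[g]
      f2 <- tr$frames[g + 1]
      p1 <- tr$pos[g, ]
      p2 <- tr$pos[g + 1, ]
      base <- tr$coords[[g]]
      for (tm in (f1 + 1):(f2 - 1)) {
        w <- (tm - f1) / (f2 - f1)
        pos <- round(p1 + w * (p2 - p1))
        off <- pos - round(p1)
        co <- sweep(base, 2, as.integer(off), `+`)
        inb <- rep(TRUE, nrow(co))
        for (a in seq_along(d)) inb <- inb & co[, a] >= 1 & co[, a] <= d[a]
        if (!all(inb)) {
          message("interpolated mask for track ", tr$id,
                  " clipped to image bounds at frame ", tm)
          co <- co[inb, , drop = FALSE]
        }
        if (nrow(co)) {
          lin <- co[, 1] + (co[, 2] - 1) * d[1]
          if (length(d) == 3) lin <- lin + (co[, 3] - 1) * d[1] * d[2]
          lin <- lin[masks[[tm]][lin] == 0]  # never overwrite real masks
          masks[[tm]][lin] <- tr$id
        }
      }
    }
  }
  child_of <- vapply(tracks, `[[`, numeric(1), "parent")
  drop <- vapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    length(tr$frames) == 1 && tr$parent == 0 && !(tr$id %in% child_of)
  }, logical(1))
  for (i in which(drop)) {
    tr <- tracks[[i]]
    f <- tr$frames[1]
    masks[[f]][masks[[f]] == tr$id] <- 0L
  }
  lineage$tracks <- tracks[!drop]
  lineage$masks <- masks
  lineage
}

#' Lineage records in `L B E P` form
#'
#' One row per track: label, first frame, last frame (0-based, matching
#' Cell Tracking Challenge file conventions) and parent label (0 = none).
#'
#' @param lineage a `cell_lineage`.
#' @return data.frame with columns `L`, `B`, `E`, `P`.
#' @export
lineage_records <- function(lineage) {
  df <- do.call(rbind, lapply(lineage$tracks, function(tr) {
    data.frame(L = tr$id, B = min(tr$frames) - 1L, E = max(tr$frames) - 1L,
               P = tr$parent)
  }))
  rownames(df) <- NULL
  df
}

#' @export
print.cell_lineage <- function(x, ...) {
  rec <- lineage_records(x)
  cat(sprintf("Cell lineage: %d tracks over %d frames (%d divisions)\n",
              nrow(rec), length(x$masks), sum(rec$P > 0) %/% 2))
  invisible(x)
}
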