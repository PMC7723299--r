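# Shared fixtures and independent oracles used across the test files.

# Small scene for fast property loops.
small_scene <- function(...) {
  scene_config(size = c(64, 64), n_cells = c(3, 7),
               semi_major = c(4, 7), semi_minor = c(3, 5),
               touching_fraction = 0.4, margin = 8, ...)
}

# Random two-cell mask of touching discs (random radii, direction and
# jitter); retries until the pair actually shares a border interface.
two_cell_mask <- function(size = c(40, 40), r1 = NULL, r2 = NULL) {
  d <- size
  disc <- function(ctr, r) {
    rr <- matrix(seq_len(d[1]), d[1], d[2]) - ctr[1]
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - ctr[2]
    rr^2 + cc^2 <= r^2
  }
  if (is.null(r1)) r1 <- runif(1, 4, 6)
  if (is.null(r2)) r2 <- runif(1, 4, 6)
  for (try in 1:50) {
    ctr1 <- c(d[1] / 2 + runif(1, -3, 3), d[2] / 2 + runif(1, -3, 3))
    theta <- runif(1, 0, 2 * pi)
    # centers well inside the radius sum: the first cell keeps the
    # overlap, producing the flat shared interface typical of cells
    # pressed together in crowded tissue
    dist <- runif(1, 0.7, 0.85) * (r1 + r2)
    ctr2 <- ctr1 + dist * c(cos(theta), sin(theta))
    lab <- array(0L, d)
    lab[disc(ctr1, r1)] <- 1L
    m2 <- disc(ctr2, r2) & lab == 0L
    lab[m2] <- 2L
    if (length(unique(lab[lab > 0])) == 2 && sum(lab == 2L) > 20 &&
        sum(boundary_and_border(lab)$border) >= 8) {
      return(lab)
    }
  }
  stop("could not build a touching two-cell mask")
}

# Exhaustive enumeration oracle for the matching problem: recursively try
# every decision combination with no pruning or ordering tricks, and
# return the minimum total cost. Independent of solve_matching().
enumerate_matching <- function(graph) {
  nt <- length(graph$tracks)
  decisions_of <- function(g) {
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
    dec
  }
  all_opts <- lapply(graph$tracks, decisions_of)
  best <- Inf
  rec <- function(i, used, acc) {
    if (i > nt) {
      best <<- min(best, acc)
      return()
    }
    for (dec in all_opts[[i]]) {
      if (any(dec$objects %in% used)) next
      rec(i + 1, c(used, dec$objects), acc + dec$cost)
    }
  }
  rec(1, integer(0), 0)
  best
}

# Random small match graph built directly (costs arbitrary, candidates
# random subsets, splits for random candidate pairs).
random_match_graph <- function(n_tracks, n_objects) {
  gtracks <- lapply(seq_len(n_tracks), function(i) {
    cand <- sort(sample(seq_len(n_objects),
                        sample(0:min(n_objects, 4), 1)))
    splits <- NULL
    if (length(cand) >= 2) {
      prs <- utils::combn(cand, 2)
      keep <- sample(ncol(prs), min(ncol(prs), 3))
      splits <- data.frame(n = prs[1, keep], k = prs[2, keep],
                           cost = runif(length(keep), 0, 30))
    }
    list(track_index = i, candidates = cand,
         match_cost = runif(length(cand), 0, 20),
         disappearance_cost = runif(1, 1, 25), splits = splits)
  })
  structure(list(tracks = gtracks, n_objects = n_objects,
                 appearance_cost = 0), class = "match_graph")
}

# Canonical shape of a lineage forest: every track is a node, children
# are grouped by parent, and each tree is rendered as a nested sorted
# string. Two forests are isomorphic iff the sorted multisets match.
forest_shape <- function(records) {
  canon <- function(id) {
    kids <- sort(vapply(records$L[records$P == id], canon, character(1)))
    paste0("(", paste(kids, collapse = ""), ")")
  }
  roots <- records$L[records$P == 0]
  sort(vapply(roots, canon, character(1)))
}

# Default tracking scenario used by the end-to-end checks: 20 frames,
# 10 cells, two scheduled divisions, one three-frame occlusion. Nuclei at
# the larger end of the realistic range so post-division daughters stay
# in the size regime the distance post-processing targets.
tracking_scenario <- function(seed) {
  sc <- scene_config(n_cells = c(10, 10), touching_fraction = 0.2,
                     semi_major = c(8, 11), semi_minor = c(6, 8))
  mo <- motion_config(n_frames = 20, drift = c(1, 1), walk_sd = 0.5,
                      division_events = data.frame(id = c(2, 5),
                                                   frame = c(7, 13)),
                      occlusion_events = data.frame(id = 3, start = 9,
                                                    duration = 3))
  generate_sequence(sc, mo, seed = seed)
}
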