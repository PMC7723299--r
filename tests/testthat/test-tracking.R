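test_that("tracks initialize at per-axis median positions", {
  L <- array(0L, c(5, 10))
  L[1, c(1, 2, 10)] <- 1L  # median column is 2
  L[4:5, 4:5] <- 2L
  tr <- initialize_tracks(L)
  expect_length(tr, 2)
  expect_equal(unname(tr[[1]]$roi_center), c(1, 2))
  expect_error(initialize_tracks(L, selected_ids = 9), "not present")
  sel <- initialize_tracks(L, selected_ids = 2)
  expect_length(sel, 1)
  expect_length(initialize_tracks(array(0L, c(5, 5))), 0)
})

test_that("phase correlation recovers integer circular shifts exactly", {
  set.seed(12)
  circ_shift <- function(m, s) {
    d <- dim(m)
    m[((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1,
      ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1]
  }
  expect_equal(estimate_shift(matrix(runif(64), 8, 8),
                              matrix(runif(64), 8, 8) * 0 + runif(64)) |>
                 length(), 2)
  for (i in 1:30) {
    a <- matrix(runif(64 * 64), 64, 64)
    s <- sample(-16:16, 2, replace = TRUE)
    expect_identical(estimate_shift(a, circ_shift(a, s)), as.integer(s))
  }
  expect_warning(z <- estimate_shift(matrix(1, 8, 8), matrix(runif(64), 8, 8)),
                 "degenerate")
  expect_identical(z, c(0L, 0L))
  expect_identical(suppressWarnings(
    estimate_shift(matrix(1, 8, 8), matrix(1, 8, 8))), c(0L, 0L))
})

test_that("matching cost is the distance from the predicted position", {
  expect_equal(matching_cost(c(10, 10), c(3, 0), c(13, 10)), 0)
  expect_equal(matching_cost(c(10, 10), c(0, 0), c(13, 14)), 5)
  expect_equal(matching_cost(c(4, 7), c(0, 0), c(4, 7)), 0)
})

test_that("split costs follow the three-clause division condition", {
  cfg <- tracker_config()
  # V_n=40, V_k=50, V_last=80: ratio 0.8 > 0.5; sum/parent 1.125 < 1.2;
  # separation 10 < gamma = 2*sqrt(80) ~ 17.9 -> admitted
  p_hat <- c(50, 50)
  c1 <- split_cost(c(50, 50), c(0, 0), 80, c(50, 45), 40, c(50, 55), 50,
                   cfg)
  expect_equal(c1, 0)  # midpoint (50,50) equals predicted position
  # candidate order must not matter (sorted internally)
  c1b <- split_cost(c(50, 50), c(0, 0), 80, c(50, 55), 50, c(50, 45), 40,
                    cfg)
  expect_equal(c1, c1b)
  rho <- 10 * 150
  # size ratio 10/50 = 0.2 <= alpha
  expect_equal(split_cost(c(50, 50), c(0, 0), 80, c(50, 45), 10,
                          c(50, 55), 50, cfg), rho)
  # combined size 110/80 > beta
  expect_equal(split_cost(c(50, 50), c(0, 0), 80, c(50, 45), 55,
                          c(50, 55), 55, cfg), rho)
  # daughters farther apart than gamma
  expect_equal(split_cost(c(50, 50), c(0, 0), 80, c(50, 40), 40,
                          c(50, 60), 50, cfg), rho)
  # nonzero cost: midpoint offset from prediction
  c2 <- split_cost(c(50, 50), c(2, 0), 80, c(50, 45), 40, c(50, 55), 50,
                   cfg)
  expect_equal(c2, 2)
})

test_that("the match graph links tracks only to ROI-overlapping objects", {
  L1 <- array(0L, c(60, 60)); L1[10:14, 10:14] <- 1L
  tr <- initialize_tracks(L1, tracker_config(roi_extent = 20))
  # candidates: one inside the ROI, one far outside
  L2 <- array(0L, c(60, 60))
  L2[12:16, 12:16] <- 1L
  L2[50:54, 50:54] <- 2L
  objs <- object_stats(L2)
  g <- build_match_graph(tr, objs, list(c(0L, 0L)),
                         tracker_config(roi_extent = 20), c(60, 60))
  expect_equal(g$tracks[[1]]$candidates, 1L)
  expect_equal(g$tracks[[1]]$disappearance_cost, 20)
  expect_null(g$tracks[[1]]$splits)
  # no candidates: only the disappearance edge remains
  L3 <- array(0L, c(60, 60)); L3[50:54, 50:54] <- 1L
  g2 <- build_match_graph(tr, object_stats(L3), list(c(0L, 0L)),
                          tracker_config(roi_extent = 20), c(60, 60))
  expect_length(g2$tracks[[1]]$candidates, 0)
  # two candidates in ROI: 2 match edges and one split pair
  L4 <- array(0L, c(60, 60))
  L4[8:11, 8:11] <- 1L; L4[14:17, 14:17] <- 2L
  g3 <- build_match_graph(tr, object_stats(L4), list(c(0L, 0L)),
                          tracker_config(roi_extent = 20), c(60, 60))
  expect_equal(g3$tracks[[1]]$candidates, c(1L, 2L))
  expect_equal(nrow(g3$tracks[[1]]$splits), 1)
})

test_that("exact matching equals exhaustive enumeration on random graphs", {
  set.seed(31)
  for (i in 1:150) {
    g <- random_match_graph(sample(1:4, 1), sample(1:5, 1))
    sol <- solve_matching(g)
    expect_equal(sol$total_cost, enumerate_matching(g))
    # flow conservation: one decision per track, objects used at most once
    expect_length(sol$decisions, length(g$tracks))
    used <- unlist(lapply(sol$decisions, `[[`, "objects"))
    expect_false(any(duplicated(used)))
    for (dec in sol$decisions) {
      expect_true(dec$type %in% c("match", "disappear", "split"))
      expect_length(dec$objects,
                    c(match = 1, disappear = 0, split = 2)[dec$type])
    }
    expect_setequal(c(used, sol$new_objects), seq_len(g$n_objects))
  }
})

test_that("cheap assignments, splits, and disappearances are chosen correctly", {
  # diagonal assignment on a 2x2 cost matrix
  g <- structure(list(tracks = list(
    list(track_index = 1, candidates = 1:2, match_cost = c(1, 10),
         disappearance_cost = 100, splits = NULL),
    list(track_index = 2, candidates = 1:2, match_cost = c(10, 1),
         disappearance_cost = 100, splits = NULL)),
    n_objects = 2, appearance_cost = 0), class = "match_graph")
  sol <- solve_matching(g)
  expect_equal(sol$total_cost, 2)
  expect_equal(sol$decisions[[1]]$objects, 1L)
  expect_equal(sol$decisions[[2]]$objects, 2L)
  # a split beats two appearances plus disappearance when cheap
  g2 <- structure(list(tracks = list(
    list(track_index = 1, candidates = 1:2, match_cost = c(8, 8),
         disappearance_cost = 20,
         splits = data.frame(n = 1, k = 2, cost = 2))),
    n_objects = 2, appearance_cost = 0), class = "match_graph")
  sol2 <- solve_matching(g2)
  expect_equal(sol2$decisions[[1]]$type, "split")
  expect_length(sol2$new_objects, 0)
  # a candidate farther than the disappearance cost is left to appear
  g3 <- structure(list(tracks = list(
    list(track_index = 1, candidates = 1, match_cost = 50,
         disappearance_cost = 20, splits = NULL)),
    n_objects = 1, appearance_cost = 0), class = "match_graph")
  sol3 <- solve_matching(g3)
  expect_equal(sol3$decisions[[1]]$type, "disappear")
  expect_equal(sol3$new_objects, 1L)
})

test_that("a drifting object yields one full-length track", {
  seqd <- generate_sequence(
    scene_config(n_cells = c(1, 1), touching_fraction = 0),
    motion_config(n_frames = 10, drift = c(2, 0), walk_sd = 0),
    seed = 5)
  lin <- postprocess_tracks(track_sequence(seqd$labels, seqd$images))
  rec <- lineage_records(lin)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$B, 0)
  expect_equal(rec$E, 9)
  expect_true(all(vapply(lin$masks, function(m) sum(m == 1) > 0,
                         logical(1))))
})

test_that("gaps up to delta_t are re-linked, longer gaps split the track", {
  mk_seq <- function(gap_len) {
    sc <- scene_config(size = c(80, 80), n_cells = c(2, 2),
                       touching_fraction = 0)
    mo <- motion_config(n_frames = 12, drift = c(1, 0), walk_sd = 0,
                        occlusion_events = data.frame(id = 1, start = 5,
                                                      duration = gap_len))
    generate_sequence(sc, mo, seed = 9)
  }
  s3 <- mk_seq(3)
  lin3 <- postprocess_tracks(track_sequence(s3$labels, s3$images))
  rec3 <- lineage_records(lin3)
  expect_equal(nrow(rec3), 2)  # occluded track re-linked
  expect_true(all(rec3$B == 0 & rec3$E == 11))
  # interpolated masks fill the gap
  expect_true(all(vapply(lin3$masks[5:7],
                         function(m) length(unique(m[m > 0])) == 2,
                         logical(1))))
  s4 <- mk_seq(4)
  lin4 <- postprocess_tracks(track_sequence(s4$labels, s4$images))
  rec4 <- lineage_records(lin4)
  expect_equal(nrow(rec4), 3)  # gap exceeds delta_t: two tracks
})

test_that("divisions are detected with correct parent bookkeeping", {
  sc <- scene_config(n_cells = c(6, 6), touching_fraction = 0)
  mo <- motion_config(n_frames = 12, drift = c(1, 1), walk_sd = 0.4,
                      division_events = data.frame(id = 2, frame = 6))
  gt <- generate_sequence(sc, mo, seed = 23)
  lin <- postprocess_tracks(track_sequence(gt$labels, gt$images))
  rec <- lineage_records(lin)
  expect_equal(sum(rec$P > 0), 2)  # exactly one split event
  daughters <- rec[rec$P > 0, ]
  expect_equal(length(unique(daughters$P)), 1)
  parent <- rec[rec$L == daughters$P[1], ]
  expect_true(all(parent$E < daughters$B))
  expect_equal(forest_shape(rec), forest_shape(gt$lineage))
})

test_that("post-processing interpolates gap masks and prunes singleton tracks", {
  # hand-built lineage: track with a 1-frame gap between (10,10) and (14,10)
  d <- c(30, 30)
  mk <- function(ctr) {
    m <- array(0L, d)
    m[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1)] <- 1L
    m
  }
  frames <- list(mk(c(10, 10)), array(0L, d), mk(c(14, 10)))
  lin <- track_sequence(frames, images = NULL, tracker_config(roi_extent = 30))
  rec0 <- lineage_records(lin)
  expect_equal(nrow(rec0), 1)
  post <- postprocess_tracks(lin)
  mid <- post$masks[[2]]
  expect_equal(sum(mid == 1), 9)
  co <- arrayInd(which(mid == 1), d)
  expect_equal(unname(apply(co, 2, median)), c(12, 10))
  # gapless lineages are untouched
  frames2 <- list(mk(c(10, 10)), mk(c(11, 10)))
  lin2 <- track_sequence(frames2, NULL, tracker_config(roi_extent = 30))
  post2 <- postprocess_tracks(lin2)
  expect_identical(post2$masks, lin2$masks)
  # a one-frame parentless, childless track is removed
  frames3 <- list(mk(c(10, 10)), mk(c(11, 10)), mk(c(12, 10)))
  spur <- array(0L, d); spur[25:26, 25:26] <- 2L
  frames3[[2]] <- frames3[[2]] + spur
  lin3 <- track_sequence(frames3, NULL, tracker_config(roi_extent = 10))
  post3 <- postprocess_tracks(lin3)
  rec3 <- lineage_records(post3)
  expect_equal(nrow(rec3), 1)
  expect_true(all(post3$masks[[2]][25:26, 25:26] == 0))
})
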