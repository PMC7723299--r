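test_that("Gaussian smoothing preserves constants and reproduces a kernel", {
  m <- matrix(runif(400), 20, 20)
  expect_equal(smooth_distances(list(cell = m, neighbor = m), 0)$cell, m)
  const <- matrix(0.7, 20, 20)
  sm <- smooth_distances(list(cell = const, neighbor = const), 1.5)
  expect_equal(sm$cell, const, tolerance = 1e-12)
  # delta impulse spreads into the separable sampled Gaussian profile
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  sm2 <- smooth_distances(list(cell = imp, neighbor = imp), 1.5)$cell
  w <- distseg:::gaussian_kernel(1.5)
  r <- (length(w) - 1) / 2
  expect_equal(sm2[16 + (-r:r), 16 + (-r:r)], outer(w, w),
               tolerance = 1e-12)
  expect_equal(sum(sm2), 1, tolerance = 1e-12)
})

test_that("mask extraction uses a strict threshold", {
  m <- matrix(c(0.05, 0.09, 0.0900001, 0.5), 2, 2)
  mask <- extract_mask(m, 0.09)
  expect_identical(as.vector(mask), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(extract_mask(matrix(0.09, 3, 3), 0.09)))
})

test_that("seed extraction applies the cell-minus-squared-neighbor rule", {
  cellm <- matrix(0, 10, 10); nbm <- matrix(0, 10, 10)
  cellm[5, 5] <- 0.9; nbm[5, 5] <- 0.6  # 0.9 - 0.36 = 0.54 > 0.5
  cellm[2, 2] <- 0.9; nbm[2, 2] <- 0.7  # 0.9 - 0.49 = 0.41: no seed
  seeds <- extract_seeds(list(cell = cellm, neighbor = nbm),
                         min_seed_area = 1)
  expect_true(seeds[5, 5] > 0)
  expect_identical(seeds[2, 2], 0L)
  # with exponent 1 the same pixel fails (0.9 - 0.6 = 0.3)
  s1 <- extract_seeds(list(cell = cellm, neighbor = nbm),
                      neighbor_exponent = 1, min_seed_area = 1)
  expect_identical(s1[5, 5], 0L)
})

test_that("seed components below the minimum area never survive", {
  set.seed(21)
  for (i in 1:25) {
    cellm <- matrix(runif(900), 30, 30)
    seeds <- extract_seeds(list(cell = cellm,
                                neighbor = matrix(0, 30, 30)),
                           rho_seed = 0.8, min_seed_area = 3)
    if (any(seeds > 0)) {
      expect_true(all(tabulate(seeds[seeds > 0]) == 0 |
                        tabulate(seeds[seeds > 0]) >= 3))
    }
    # a deliberate 2-pixel component is removed
    cellm2 <- matrix(0, 10, 10); cellm2[4, 4:5] <- 1
    s2 <- extract_seeds(list(cell = cellm2, neighbor = matrix(0, 10, 10)))
    expect_true(all(s2 == 0))
  }
})

test_that("watershed floods every mask pixel from exactly one seed", {
  # one seed, connected mask: the whole mask takes that label
  mask <- matrix(FALSE, 12, 12); mask[3:10, 3:10] <- TRUE
  seeds <- array(0L, c(12, 12)); seeds[6, 6] <- 1L
  hm <- matrix(runif(144), 12, 12)
  ws <- watershed_assign(mask, seeds, hm)
  expect_true(all(ws[mask] == 1))
  expect_true(all(ws[!mask] == 0))
  # two seeds in disjoint components cannot leak across background
  mask2 <- matrix(FALSE, 10, 20)
  mask2[3:8, 3:8] <- TRUE; mask2[3:8, 13:18] <- TRUE
  seeds2 <- array(0L, c(10, 20)); seeds2[5, 5] <- 1L; seeds2[5, 15] <- 2L
  ws2 <- watershed_assign(mask2, seeds2, matrix(1, 10, 20))
  expect_true(all(ws2[, 3:8][mask2[, 3:8]] == 1))
  expect_true(all(ws2[, 13:18][mask2[, 13:18]] == 2))
  expect_warning(watershed_assign(mask, array(0L, c(12, 12)), hm),
                 "no seeds")
})

test_that("touching equal discs split close to the geometric interface", {
  lab <- array(0L, c(40, 60))
  disc <- function(ctr, r) {
    rr <- matrix(seq_len(40), 40, 60) - ctr[1]
    cc <- matrix(seq_len(60), 40, 60, byrow = TRUE) - ctr[2]
    rr^2 + cc^2 <= r^2
  }
  lab[disc(c(20, 22), 9)] <- 1L
  m2 <- disc(c(20, 39), 9); lab[m2 & lab == 0L] <- 2L
  pair <- perfect_predictions(lab)
  sm <- smooth_distances(pair, c(1.5, 1.5))
  seeds <- extract_seeds(sm)
  expect_equal(length(unique(seeds[seeds > 0])), 2)
  ws <- watershed_assign(extract_mask(sm$cell), seeds, sm$cell)
  expect_equal(length(unique(ws[ws > 0])), 2)
  # agreement with ground truth as label-matched pixel accuracy
  agree <- 0; tot <- 0
  for (id in 1:2) {
    over <- ws[lab == id]; over <- over[over > 0]
    best <- as.integer(names(which.max(table(over))))
    agree <- agree + sum(ws[lab == id] == best)
    tot <- tot + sum(lab == id)
  }
  expect_gt(agree / tot, 0.95)
})

test_that("raising thresholds is monotone for seeds and mask", {
  set.seed(8)
  fr <- generate_frame(small_scene(), seed = 17)
  sm <- smooth_distances(perfect_predictions(fr$labels))
  # seed component count never decreases with the threshold on this map
  counts <- vapply(c(0.3, 0.4, 0.5, 0.6), function(r) {
    s <- extract_seeds(sm, rho_seed = r, min_seed_area = 1)
    length(unique(s[s > 0]))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  masks <- lapply(c(0.05, 0.09, 0.2, 0.4), function(r)
    extract_mask(sm$cell, r))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))  # raising never grows
  }
})

test_that("a zero neighbor map degrades seeding to pure cell distance", {
  fr <- generate_frame(small_scene(), seed = 29)
  pair <- perfect_predictions(fr$labels)
  sm <- smooth_distances(pair)
  zero <- smooth_distances(list(cell = pair$cell,
                                neighbor = array(0, dim(pair$cell))))
  s_zero <- extract_seeds(zero)
  s_cell_only <- label_components(zero$cell > 0.5, "full")
  sz <- tabulate(s_cell_only)
  s_cell_only[s_cell_only %in% which(sz < 3 & sz > 0)] <- 0L
  expect_equal(length(unique(s_zero[s_zero > 0])),
               length(unique(s_cell_only[s_cell_only > 0])))
})

test_that("segmentation round-trip recovers objects from perfect predictions", {
  set.seed(14)
  n_img <- 12
  exact <- 0; ious <- numeric(0)
  for (i in seq_len(n_img)) {
    fr <- generate_frame(scene_config(), seed = 4000 + i)
    p <- make_perfect_predictor(fr$labels)
    seg <- segment_frames(list(fr$image), p)[[1]]
    n_gt <- length(unique(fr$labels[fr$labels > 0]))
    n_seg <- length(unique(seg[seg > 0]))
    if (n_gt == n_seg) exact <- exact + 1
    ious <- c(ious, seg_measure(fr$labels, seg))
  }
  expect_gte(exact / n_img, 0.95)
  expect_gte(mean(ious), 0.85)
  # labels partition the mask
  fr <- generate_frame(scene_config(), seed = 4001)
  sm <- smooth_distances(perfect_predictions(fr$labels))
  mask <- extract_mask(sm$cell)
  seeds <- extract_seeds(sm)
  ws <- watershed_assign(mask, seeds, sm$cell)
  expect_true(all(ws[mask] > 0))
  expect_true(all(ws[!mask] == 0))
  expect_equal(length(unique(ws[ws > 0])),
               length(unique(seeds[seeds > 0 & mask])))
})

test_that("empty frames segment to empty label images", {
  img <- matrix(0.1, 32, 32)
  p <- function(image, index) list(cell = matrix(0, 32, 32),
                                   neighbor = matrix(0, 32, 32))
  seg <- segment_frames(list(img), p)
  expect_true(all(seg[[1]] == 0))
})

test_that("3D volumes are segmented slice-wise and merged cells re-split", {
  d <- c(36, 36, 26)
  lab <- array(0L, d)
  sphere <- function(ctr, r) {
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    which((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2)
  }
  lab[sphere(c(18, 18, 8), 6)] <- 1L
  s2 <- sphere(c(18, 18, 17), 6); lab[s2[lab[s2] == 0L]] <- 2L
  pair <- perfect_predictions(lab)
  sm <- smooth_distances(pair, c(1.5, 1.5, 0.5))
  ws <- watershed_assign(extract_mask(sm$cell), extract_seeds(sm), sm$cell)
  expect_equal(length(unique(ws[ws > 0])), 2)
  # merge them artificially plus one normal-size object, then re-split
  merged <- ws; merged[merged == 2L] <- 1L
  merged[2:5, 2:5, 2:5] <- 7L
  sp <- split_merged_3d(merged, sm, postprocess_config())
  expect_equal(length(unique(sp[sp > 0])), 3)
  # object near the mean volume is untouched
  expect_true(all(sp[2:5, 2:5, 2:5] == 7L))
  # a genuinely unimodal big object survives at the threshold cap
  single <- array(0L, d)
  single[sphere(c(18, 18, 13), 8)] <- 1L
  single[2:4, 2:4, 2:4] <- 2L
  smp <- smooth_distances(perfect_predictions(single), c(1.5, 1.5, 0.5))
  expect_message(sp2 <- split_merged_3d(single, smp, postprocess_config()),
                 "kept unchanged")
  expect_equal(sort(unique(as.vector(sp2[sp2 > 0]))), c(1L, 2L))
})
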