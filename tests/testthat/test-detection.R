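test_that("binary morphology behaves as set morphology with disk elements", {
  pt <- matrix(0, 11, 11); pt[6, 6] <- 1
  expect_equal(close_disk(pt, 2), pt)         # closing is extensive on a point
  expect_equal(sum(open_disk(pt, 2)), 0)      # opening removes small objects
  big <- make_disk_atom(4, c(10, 10), c(20, 20))
  expect_equal(open_disk(big, 3), big)        # opening keeps large disks
  # two bar fragments 1 px apart are merged by a radius-2 closing
  frag <- matrix(0, 9, 9); frag[4:6, 3] <- 1; frag[4:6, 5] <- 1
  closed <- close_disk(frag, 2)
  expect_equal(closed[5, 4], 1)
  expect_equal(max(label_components(closed)), 1)
})

test_that("connected component labeling is 8-connected", {
  z <- matrix(0, 5, 5); z[2, 2] <- 1; z[3, 3] <- 1  # diagonal touch
  expect_equal(max(label_components(z)), 1)
  z2 <- matrix(0, 5, 5); z2[1, 1] <- 1; z2[5, 5] <- 1; z2[1, 5] <- 1
  expect_equal(max(label_components(z2)), 3)
  expect_equal(label_components(matrix(0, 4, 4)), matrix(0L, 4, 4))
})

test_that("dominant radius is the per-pixel argmax with small-radius ties", {
  d <- build_dictionary(3, 5, 1)
  z <- array(0, c(4, 4, 3))
  expect_equal(dominant_radius_map(z, d), matrix(3, 4, 4))  # all-tie rule
  z[2, 2, 3] <- 0.9; z[2, 2, 1] <- 0.1
  expect_equal(dominant_radius_map(z, d)[2, 2], 5)
  set.seed(51)
  zr <- array(runif(48), c(4, 4, 3))
  dm <- dominant_radius_map(zr, d)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(dm[i, j], d$radii[which.max(zr[i, j, ])])
  }
})

test_that("coefficient merging sums over radii", {
  expect_equal(merge_coefficients(array(0, c(3, 3, 2))), matrix(0, 3, 3))
  one <- array(runif(9), c(3, 3, 1))
  expect_equal(merge_coefficients(one), one[, , 1])
  set.seed(52)
  zr <- array(runif(36), c(3, 4, 3))
  expect_equal(merge_coefficients(zr), zr[, , 1] + zr[, , 2] + zr[, , 3])
})

test_that("clutter mask removes only oversized objects", {
  d <- build_dictionary(2, 3)
  cfg <- detection_config(clutter_opening_radius = 5)
  small <- make_disk_atom(3, c(10, 10), c(40, 40))
  expect_equal(clutter_mask(small, cfg, d), small)  # opening is empty
  blob <- make_disk_atom(15, c(20, 20), c(40, 40))
  cm <- clutter_mask(blob, cfg, d)
  # morphology oracle via set operations: opened = dilate(erode(blob))
  opened <- dilate_disk(erode_disk(blob, 5), 5)
  expect_equal(cm, (blob > 0 & opened == 0) * 1)
  expect_equal(cm[20, 20], 0)  # interior of the clutter blob is masked out
  expect_equal(clutter_mask(matrix(0, 20, 20), cfg, d), matrix(0, 20, 20))
  bad <- detection_config(clutter_opening_radius = 2)
  expect_error(clutter_mask(small, bad, d), "exceed")
})

test_that("candidate components follow binarize, close, mask, label", {
  d <- build_dictionary(2, 3)
  cfg <- detection_config(clutter_opening_radius = 6)
  ub <- pmax(make_disk_atom(4, c(5, 5), c(20, 20)),
             make_disk_atom(4, c(15, 15), c(20, 20)),
             make_disk_atom(2, c(10, 10), c(20, 20)))
  expect_equal(candidate_components(matrix(0, 20, 20), ub, cfg, d), list())
  # two well-separated unimodal peaks -> 2 components
  Tm <- matrix(0, 20, 20)
  Tm[5:6, 5:6] <- 0.9; Tm[15:16, 15:16] <- 0.8
  Tm[10, 10] <- 0.05  # weak background response
  comps <- candidate_components(Tm, ub, cfg, d)
  expect_length(comps, 2)
  # bar fragments 1 px apart merge into one component through the closing
  T2 <- matrix(0, 20, 20); T2[9:11, 8] <- 1; T2[9:11, 10] <- 1
  comps2 <- candidate_components(T2, ub, detection_config(
    t_binarize_mode = "fixed", t_binarize_level = 0.5,
    closing_radius = 2, clutter_opening_radius = 6), d)
  expect_length(comps2, 1)
})

test_that("component scoring averages intensity and takes the modal radius", {
  pre <- matrix(1, 10, 10)
  rmap <- matrix(3, 10, 10)
  comp <- which(make_disk_atom(2, c(5, 5), c(10, 10)) == 1, arr.ind = TRUE)
  sc <- score_components(list(comp), pre, rmap)
  expect_equal(sc$score, 1)
  expect_equal(sc$row, 5); expect_equal(sc$col, 5)
  expect_equal(sc$radius_px, 3)

  single <- matrix(c(4L, 7L), 1, 2)
  pre2 <- matrix(runif(100), 10, 10)
  sc2 <- score_components(list(single), pre2, rmap)
  expect_equal(sc2$score, pre2[4, 7])

  set.seed(53)
  comp3 <- which(matrix(runif(100) > 0.6, 10, 10), arr.ind = TRUE)
  rmap3 <- matrix(sample(c(3, 5), 100, replace = TRUE), 10, 10)
  sc3 <- score_components(list(comp3), pre2, rmap3)
  vals <- numeric(0); rads <- numeric(0)
  for (k in seq_len(nrow(comp3))) {
    vals <- c(vals, pre2[comp3[k, 1], comp3[k, 2]])
    rads <- c(rads, rmap3[comp3[k, 1], comp3[k, 2]])
  }
  expect_equal(sc3$score, mean(vals))
  expect_equal(sc3$row, mean(comp3[, 1]))
  tabr <- table(rads)
  expect_equal(sc3$radius_px,
               min(as.numeric(names(tabr)[tabr == max(tabr)])))
})

test_that("greedy suppression matches the literal list-mutation procedure", {
  empty <- tibble::tibble(row = numeric(0), col = numeric(0),
                          radius_px = numeric(0), score = numeric(0),
                          area = integer(0))
  expect_equal(nrow(greedy_select(empty)), 0)

  two <- tibble::tibble(row = c(5, 5), col = c(5, 6), radius_px = c(5, 5),
                        score = c(0.9, 0.8), area = c(10L, 10L))
  out <- greedy_select(two)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)

  set.seed(54)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    cand <- tibble::tibble(row = runif(n, 1, 30), col = runif(n, 1, 30),
                           radius_px = sample(3:6, n, replace = TRUE),
                           score = round(runif(n), 2),
                           area = sample(5:40, n, replace = TRUE))
    expect_equal(as.data.frame(greedy_select(cand)),
                 as.data.frame(bf_greedy(cand)),
                 ignore_attr = TRUE)
  }
})

test_that("no detection lies within an earlier, higher-scored one's radius", {
  set.seed(55)
  cand <- tibble::tibble(row = runif(25, 1, 40), col = runif(25, 1, 40),
                         radius_px = sample(3:8, 25, replace = TRUE),
                         score = runif(25), area = sample(5:50, 25, TRUE))
  out <- greedy_select(cand)
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      d_prev <- sqrt((out$row[seq_len(i - 1)] - out$row[i])^2 +
                     (out$col[seq_len(i - 1)] - out$col[i])^2)
      expect_true(all(d_prev > out$radius_px[seq_len(i - 1)]))
    }
  }
  expect_lte(nrow(out), nrow(cand))
})

test_that("the full detection chain finds isolated disks and skips clutter", {
  # blank segmentation -> no detections
  d <- build_dictionary(4, 8)
  blank <- structure(list(u = matrix(0, 40, 40),
                          t = array(0, c(40, 40, length(d$radii))),
                          dict = d, params = energy_params(c_fg = .9, c_bg = .1),
                          energy_trace = numeric(0), converged = TRUE,
                          image = matrix(0.1, 40, 40)),
                     class = "nuclei_segmentation")
  expect_equal(nrow(detect(blank)), 0)

  # five isolated clean disks
  fx <- generate_fixture(fixture_config(dim = c(128, 128), n_nuclei = 5,
    radius_range = c(6, 6), touching_fraction = 0, blur_sigma = 0,
    illumination_gradient = 0, noise_sd = 0, seed = 9))
  seg <- segment(fx$image, build_dictionary(4, 8))
  det <- detect(seg)
  expect_equal(nrow(det), 5)
  m <- match_detections(det, fx$truth, match_radius_um = 2, pixel_size_um = 1)
  expect_equal(m$tp, 5)
  expect_true(all(abs(det$radius_px - 6) <= 1))

  # detect is deterministic
  det2 <- detect(seg)
  expect_identical(det, det2)

  # touching pair plus an oversized clutter blob -> exactly the 2 nuclei
  fx2 <- generate_fixture(fixture_config(dim = c(160, 160), n_nuclei = 2,
    radius_range = c(10, 10), touching_fraction = 1, clutter_blobs = 1,
    clutter_radius_multiplier = 2, seed = 3))
  out <- detect_nuclei(fx2$image, run_config(r_min = 8, r_max = 12))
  expect_equal(nrow(out$detections), 2)
  m2 <- match_detections(out$detections, fx2$truth)
  expect_equal(m2$tp, 2)
  expect_equal(m2$fp, 0)
})
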