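test_that("intensity estimation splits the histogram at the Otsu threshold", {
  img <- matrix(c(rep(0.1, 90), rep(0.9, 10)), 10, 10)
  ci <- estimate_intensities(img)
  expect_equal(ci$c_bg, 0.1)
  expect_equal(ci$c_fg, 0.9)

  disk <- clean_disk_image(c(21, 21), rbind(c(11, 11)), 5, fg = 0.8, bg = 0.2)
  ci2 <- estimate_intensities(disk)
  expect_equal(ci2$c_fg, 0.8)
  expect_equal(ci2$c_bg, 0.2)

  set.seed(41)
  mix <- matrix(c(rnorm(300, 0.25, 0.03), rnorm(100, 0.75, 0.03)), 20, 20)
  mix <- pmin(pmax(mix, 0), 1)
  thr <- bf_otsu(as.vector(mix))
  ci3 <- estimate_intensities(mix)
  expect_equal(ci3$c_fg, mean(mix[mix > thr]), tolerance = 1e-6)
  expect_equal(ci3$c_bg, mean(mix[mix <= thr]), tolerance = 1e-6)
  expect_error(estimate_intensities(matrix(0.4, 5, 5)), "constant")
})

test_that("data term follows the two-phase quadratic contrast", {
  p <- energy_params(c_fg = 0.8, c_bg = 0.2)
  expect_equal(data_term(matrix(0.8, 2, 2), p)[1, 1], -(0.2 - 0.8)^2)
  expect_equal(data_term(matrix(0.5, 2, 2), p)[1, 1], 0)
  set.seed(42)
  f <- matrix(runif(12), 3, 4)
  expect_equal(data_term(f, p), (0.8 - f)^2 - (0.2 - f)^2, tolerance = 1e-12)
})

test_that("energy matches a term-by-term brute-force evaluation", {
  d <- build_dictionary(1, 2, 1)
  p <- energy_params(mu = 1.3, lambda_sparsity = 0.7, alpha_coupling = 0.9,
                     c_fg = 0.8, c_bg = 0.2)
  img0 <- matrix(0.5, 4, 4)
  z <- array(0, c(4, 4, 2))
  expect_equal(energy(matrix(0, 4, 4), z, img0, d, p), 0)

  # u == 1, t == 0 on a constant image: TV vanishes, only data + coupling
  imgc <- matrix(0.6, 5, 5)
  s <- (0.8 - 0.6)^2 - (0.2 - 0.6)^2
  zz <- array(0, c(5, 5, 2))
  expect_equal(energy(matrix(1, 5, 5), zz, imgc, d, p),
               1.3 * 25 * s + 0.9 / 2 * 25, tolerance = 1e-10)

  set.seed(43)
  u <- matrix(runif(64), 8, 8)
  tt <- array(runif(128), c(8, 8, 2))
  img <- matrix(runif(64), 8, 8)
  s2 <- (0.8 - img)^2 - (0.2 - img)^2
  brute <- bf_tv(u) + 1.3 * bf_inner(u, s2) + 0.7 * sum(abs(tt)) +
    0.9 / 2 * sum((u - bf_synthesize(tt, d$radii))^2)
  expect_equal(energy(u, tt, img, d, p), brute, tolerance = 1e-10)
})

test_that("labeling update is driven by consistent forces and stays in [0,1]", {
  d <- build_dictionary(1, 1)
  p <- energy_params(c_fg = 0.9, c_bg = 0.1, inner_u_iters = 200)
  # strongly negative data term + full synthesis: everything says foreground
  img_fg <- matrix(0.9, 8, 8)
  t_full <- array(0, c(8, 8, 1))
  t_full[, , 1] <- 1
  u <- update_u(matrix(0.5, 8, 8), t_full, img_fg, d, p)
  expect_true(all(u > 0.95))
  # strongly positive data term + empty synthesis: everything background
  img_bg <- matrix(0.1, 8, 8)
  u2 <- update_u(matrix(0.5, 8, 8), array(0, c(8, 8, 1)), img_bg, d, p)
  expect_true(all(u2 < 0.05))
  expect_true(all(u >= 0 & u <= 1) && all(u2 >= 0 & u2 <= 1))
})

test_that("1x1 labeling update reaches the clipped closed-form minimizer", {
  # TV vanishes on one pixel: argmin mu*s*u + (alpha/2)(u - Dt)^2 over [0,1]
  d <- build_dictionary(1, 1)
  for (val in c(0.15, 0.45, 0.85)) {
    p <- energy_params(mu = 1.7, alpha_coupling = 0.8,
                       c_fg = 0.9, c_bg = 0.1, inner_u_iters = 300)
    img <- matrix(val, 1, 1)
    tt <- array(0.6, c(1, 1, 1))  # Dt = 0.6 (atom clipped to one pixel)
    s <- (0.9 - val)^2 - (0.1 - val)^2
    expected <- min(max(0.6 - 1.7 * s / 0.8, 0), 1)
    u <- update_u(matrix(0.5, 1, 1), tt, img, d, p)
    expect_equal(u[1, 1], expected, tolerance = 1e-6)
  }
})

test_that("coefficient update solves scalar instances exactly", {
  d <- build_dictionary(1, 1)  # on a 1x1 grid the atom clips to one pixel
  # u == 0 keeps t at zero
  p0 <- energy_params(c_fg = 0.9, c_bg = 0.1)
  t0 <- update_t(matrix(0, 6, 6), array(0, c(6, 6, 1)), d, p0)
  expect_equal(t0, array(0, c(6, 6, 1)))

  # lambda = 0, single atom: coefficient -> <u, atom>/||atom||^2 = 1
  d2 <- build_dictionary(2, 2)
  u <- make_disk_atom(2, c(5, 5), c(9, 9))
  p1 <- energy_params(lambda_sparsity = 0, alpha_coupling = 0.5,
                      c_fg = 0.9, c_bg = 0.1, inner_t_iters = 400)
  t1 <- update_t(u, array(0, c(9, 9, 1)), d2, p1)
  expect_equal(t1[5, 5, 1], 1, tolerance = 1e-5)

  # scalar prox: argmin lambda*|t| + (alpha/2)(u - t)^2 over [0,1],
  # compared against a dense grid search
  for (uval in c(0.2, 0.6, 0.95)) {
    lam <- 0.12; alf <- 0.6
    p2 <- energy_params(lambda_sparsity = lam, alpha_coupling = alf,
                        c_fg = 0.9, c_bg = 0.1, inner_t_iters = 60)
    ts <- update_t(matrix(uval, 1, 1), array(0, c(1, 1, 1)), d, p2)
    grid <- seq(0, 1, by = 1e-4)
    brute <- grid[which.min(lam * abs(grid) + alf / 2 * (uval - grid)^2)]
    expect_equal(ts[1, 1, 1], brute, tolerance = 1e-3)
  }
})

test_that("updates never leave the [0,1] box, exactly", {
  set.seed(44)
  d <- build_dictionary(2, 4, 1)
  img <- matrix(runif(400), 20, 20)
  p <- energy_params(c_fg = 0.8, c_bg = 0.2, inner_t_iters = 3)
  u <- matrix(runif(400), 20, 20)
  tt <- array(runif(1200), c(20, 20, 3))
  for (rep in 1:3) {
    u <- update_u(u, tt, img, d, p)
    tt <- update_t(u, tt, d, p)
    expect_true(all(u >= 0 & u <= 1))
    expect_true(all(tt >= 0 & tt <= 1))
  }
})

test_that("segmentation recovers a bright disk with concentrated coefficients", {
  img <- clean_disk_image(c(40, 40), rbind(c(20, 20)), 8)
  d <- build_dictionary(6, 10, 1)
  seg <- segment(img, d)
  expect_s3_class(seg, "nuclei_segmentation")
  bin <- threshold_u(seg$u, 0.5)
  expect_gte(dice(bin, make_disk_atom(8, c(20, 20), c(40, 40))), 0.9)
  # coefficient mass concentrates within 2 px of the true center
  Tm <- merge_coefficients(seg$t)
  peak <- which(Tm == max(Tm), arr.ind = TRUE)[1, ]
  expect_lte(sqrt(sum((peak - c(20, 20))^2)), 2)
})

test_that("energy trace is non-increasing on random fixtures", {
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_config(dim = c(48, 48), n_nuclei = 2,
      radius_range = c(5, 7), touching_fraction = 0, blur_sigma = 1,
      illumination_gradient = 0.2, noise_sd = 0.05, seed = seed))
    d <- build_dictionary(4, 8, 1)
    p <- energy_params(max_outer_iters = 60)
    seg <- suppressWarnings(segment(fx$image, d, p))
    tr <- seg$energy_trace
    expect_true(all(diff(tr) <= 1e-9 * max(abs(tr[1]), 1)))
    expect_true(all(seg$u >= 0 & seg$u <= 1))
    expect_true(all(seg$t >= 0 & seg$t <= 1))
  }
})

test_that("the minimizer does not depend on the initialization", {
  fx <- generate_fixture(fixture_config(dim = c(96, 96), n_nuclei = 3,
    radius_range = c(8, 8), seed = 5))
  d <- build_dictionary(6, 10)
  pre <- preprocess(fx$image, preprocess_config(15))
  p <- energy_params(tol = 1e-7, max_outer_iters = 800)
  s1 <- suppressWarnings(segment(pre, d, p, u_init = 0.5))
  s2 <- suppressWarnings(segment(pre, d, p, u_init = 0))
  b1 <- threshold_u(s1$u, 0.5); b2 <- threshold_u(s2$u, 0.5)
  expect_equal(dice(b1, b2), 1)
})

test_that("without the shape prior the model degenerates to plain ACWE", {
  fx <- generate_fixture(fixture_config(dim = c(96, 96), n_nuclei = 3,
    radius_range = c(8, 8), touching_fraction = 0, blur_sigma = 0,
    illumination_gradient = 0, noise_sd = 0, seed = 7))
  p <- energy_params(mu = 3, lambda_sparsity = 0, alpha_coupling = 1e-3,
                     tol = 1e-7, max_outer_iters = 800)
  seg <- suppressWarnings(segment(fx$image, build_dictionary(6, 10), p))
  thr <- bf_otsu(as.vector(fx$image))
  otsu_mask <- (fx$image > thr) * 1
  expect_equal(dice(threshold_u(seg$u, 0.5), otsu_mask), 1)
})

test_that("degenerate inputs short-circuit with a warning", {
  d <- build_dictionary(2, 3)
  expect_warning(seg <- segment(matrix(0.3, 12, 12), d), "constant")
  expect_equal(sum(threshold_u(seg$u, 0.5)), 0)
  expect_true(seg$converged)
})

test_that("thresholding is strict and validates its level", {
  expect_equal(threshold_u(matrix(1, 3, 3), 0.5), matrix(1, 3, 3))
  expect_equal(threshold_u(matrix(0.5, 3, 3), 0.5), matrix(0, 3, 3))
  set.seed(45)
  u <- matrix(runif(49), 7, 7)
  expect_equal(threshold_u(u, 0.5), (u > 0.5) * 1)
  expect_error(threshold_u(u, 0), "strictly inside")
  expect_error(threshold_u(u, 1), "strictly inside")
})

test_that("tidy and glance summarize a fit", {
  img <- clean_disk_image(c(30, 30), rbind(c(15, 15)), 6)
  seg <- segment(img, build_dictionary(5, 7))
  td <- tidy(seg)
  expect_equal(td$iteration[1], 0L)
  expect_equal(td$energy, seg$energy_trace)
  gl <- glance(seg)
  expect_equal(gl$height, 30)
  expect_true(gl$converged)
  expect_gt(gl$foreground_px, 0)
})
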