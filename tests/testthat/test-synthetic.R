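test_that("simulate_image honours degenerate specs and the delta kernel", {
  empty <- simulate_image(synthetic_image_spec(size = c(32, 32),
                                               n_features = 0,
                                               feature_length = 10,
                                               tip_sigma = 0,
                                               scanline_sd = 0, noise_sd = 0,
                                               seed = 1))
  expect_equal(empty$heightmap$heights, matrix(0, 32, 32))
  expect_equal(nrow(empty$ground_truth$features), 0L)

  one <- simulate_image(synthetic_image_spec(size = c(64, 64), n_features = 1,
                                             feature_length = 20,
                                             mean_angle = 0, angle_sd = 0,
                                             feature_height = 3, tip_sigma = 0,
                                             scanline_sd = 0, noise_sd = 0,
                                             seed = 7))
  h <- one$heightmap$heights
  expect_setequal(unique(as.vector(h)), c(0, 3))
  # horizontal feature: all painted pixels share one row
  painted <- which(h == 3, arr.ind = TRUE)
  expect_equal(length(unique(painted[, 1])), 1L)
  expect_equal(nrow(painted), 21L)  # 20 px length inclusive of both ends
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- synthetic_image_spec(size = c(64, 64), n_features = 40,
                               feature_length = 25, seed = 123)
  a <- simulate_image(spec)
  b <- simulate_image(spec)
  expect_identical(a$heightmap$heights, b$heightmap$heights)
  expect_identical(a$ground_truth$features, b$ground_truth$features)

  p1 <- simulate_pore_image(c(32, 32), 1,
                            list(list(origin = c(4, 4), side = 5, depth = 1)),
                            noise_sd = 0.1, seed = 3)
  p2 <- simulate_pore_image(c(32, 32), 1,
                            list(list(origin = c(4, 4), side = 5, depth = 1)),
                            noise_sd = 0.1, seed = 3)
  expect_identical(p1$heightmap$heights, p2$heightmap$heights)

  cal <- demo_calibration()
  comp <- data.frame(mw = c(2e5, 1e3), fraction = c(0.5, 0.5),
                     width = c(0.1, 0.1))
  c1 <- simulate_chromatogram(comp, cal, noise_sd = 1e-3, seed = 9)
  c2 <- simulate_chromatogram(comp, cal, noise_sd = 1e-3, seed = 9)
  expect_identical(c1$chromatogram$signal, c2$chromatogram$signal)
})

test_that("tip convolution preserves total mass", {
  spec0 <- synthetic_image_spec(size = c(96, 96), n_features = 60,
                                tip_sigma = 0, scanline_sd = 0, noise_sd = 0,
                                feature_length = 30, seed = 42)
  spec2 <- synthetic_image_spec(size = c(96, 96), n_features = 60,
                                tip_sigma = 2.5, scanline_sd = 0, noise_sd = 0,
                                feature_length = 30, seed = 42)
  s0 <- sum(simulate_image(spec0)$heightmap$heights)
  s2 <- sum(simulate_image(spec2)$heightmap$heights)
  expect_equal(s2, s0, tolerance = 1e-9)
})

test_that("simulate_pore_image builds exact depressions and rejects bad specs", {
  sim <- simulate_pore_image(c(64, 64), 1,
                             list(list(origin = c(10, 10), side = 5,
                                       depth = 2)))
  expect_equal(sum(sim$heightmap$heights < 0), 25L)
  expect_equal(sim$ground_truth$pixel_area, 25L)

  flat <- simulate_pore_image(c(16, 16), 1, list())
  expect_equal(flat$heightmap$heights, matrix(0, 16, 16))

  expect_pg_error(
    simulate_pore_image(c(32, 32), 1,
                        list(list(origin = c(4, 4), side = 6, depth = 1),
                             list(origin = c(8, 8), side = 6, depth = 1))),
    "pgafm_spec_error")
  expect_pg_error(
    simulate_pore_image(c(16, 16), 1,
                        list(list(origin = c(14, 14), side = 5, depth = 1))),
    "pgafm_spec_error")

  # end to end: three depressions recovered with constructed areas
  three <- simulate_pore_image(c(64, 64), 1, list(
    list(origin = c(5, 5), side = 3, depth = 2),
    list(origin = c(20, 20), side = 5, depth = 2),
    list(origin = c(40, 40), side = 10, depth = 2)))
  ps <- detect_pores(three$heightmap, window = 31, sensitivity = 0.5)
  expect_equal(sort(ps$pores$area_nm2), sort(three$ground_truth$area_nm2))
})

test_that("simulate_chromatogram places mass fractions where calibration says", {
  cal <- demo_calibration()
  single <- simulate_chromatogram(data.frame(mw = 1e5, fraction = 1,
                                             width = 0.15), cal)
  peak_v <- predict_volume(cal, 1e5)
  expect_equal(fraction_before(single$chromatogram, peak_v + 0.7), 100,
               tolerance = 0.1)

  two_eq <- simulate_chromatogram(
    data.frame(mw = c(1e6, 1e2), fraction = c(0.5, 0.5), width = c(0.1, 0.1)),
    cal)
  mid <- mean(predict_volume(cal, c(1e6, 1e2)))
  expect_equal(fraction_before(two_eq$chromatogram, mid), 50, tolerance = 0.5)

  split <- simulate_chromatogram(
    data.frame(mw = c(1e6, 1e2), fraction = c(0.4, 0.6), width = c(0.1, 0.1)),
    cal)
  expect_equal(fraction_before(split$chromatogram, mid), 40, tolerance = 0.4)

  expect_pg_error(
    simulate_chromatogram(data.frame(mw = c(1e5, 1e3),
                                     fraction = c(0.7, 0.6),
                                     width = c(0.1, 0.1)), cal),
    "pgafm_spec_error")
})
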