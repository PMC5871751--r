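test_that("gradient_field matches analytic derivatives", {
  # z = x ramp
  z <- outer(seq_len(10), seq_len(12), function(y, x) x * 1.0)
  gf <- gradient_field(heightmap(z, 1))
  expect_equal(gf$gx, matrix(1, 10, 12))
  expect_equal(gf$gy, matrix(0, 10, 12))

  gf0 <- gradient_field(heightmap(matrix(2, 5, 5), 1))
  expect_equal(gf0$gx, matrix(0, 5, 5))
  expect_equal(gf0$gy, matrix(0, 5, 5))

  # z = sin(2*pi*x/16): interior central-difference error is bounded by
  # max|f'''| h^2 / 6 = (2*pi/16)^3 / 6 < 0.026
  z <- outer(seq_len(32), seq_len(64), function(y, x) sin(2 * pi * x / 16))
  gf <- gradient_field(heightmap(z, 1))
  analytic <- outer(seq_len(32), seq_len(64),
                    function(y, x) 2 * pi / 16 * cos(2 * pi * x / 16))
  err <- abs(gf$gx - analytic)[, 2:63]
  expect_lt(max(err), 0.026)

  expect_pg_error(gradient_field(heightmap(matrix(0, 2, 5), 1)),
                  "pgafm_size_error")
})

test_that("orientation_histogram bins gradients by direction with magnitude weight", {
  z <- outer(seq_len(16), seq_len(16), function(y, x) 1.0 * x)
  ph <- orientation_histogram(gradient_field(heightmap(z, 1)), n_bins = 36L)
  expect_equal(sum(ph$weights > 0), 1L)
  expect_equal(which.max(ph$weights), 1L)  # angle 0 lives in the first bin

  gf <- make_gradient_field(gx = matrix(c(1, -1), 2, 8), gy = matrix(0, 2, 8))
  ph <- orientation_histogram(gf, n_bins = 8L)
  nz <- which(ph$weights > 0)
  expect_length(nz, 2L)
  expect_equal(diff(nz), 4L)                       # antipodal bins
  expect_equal(ph$weights[nz[1L]], ph$weights[nz[2L]])

  expect_pg_error(
    orientation_histogram(gradient_field(heightmap(matrix(0, 8, 8), 1))),
    "pgafm_degenerate_error")

  # aligned simulated chains: gradients concentrate perpendicular to them
  sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                             n_features = 300,
                                             mean_angle = 0, angle_sd = 5,
                                             seed = 3))
  m <- downsample_half(subtract_plane(flatten_lines(sim$heightmap)))
  ph <- orientation_histogram(gradient_field(m), n_bins = 72L)
  centres <- (seq_len(72) - 0.5) * 360 / 72
  sep <- abs(((centres - 90) + 180) %% 360 - 180)      # distance to 90 deg
  sep2 <- abs(((centres - 270) + 180) %% 360 - 180)    # distance to 270 deg
  near_perp <- pmin(sep, sep2) <= 30
  expect_gte(sum(ph$weights[near_perp]) / sum(ph$weights), 0.6)
})

test_that("fit_ellipse recovers generating ellipses and flags degeneracies", {
  # isotropic histogram -> exactly 1
  iso <- ellipse_histogram(1, 1)
  expect_equal(fit_ellipse(iso)$order_parameter, 1, tolerance = 1e-9)

  # axis-aligned 2:1 ellipse
  res <- fit_ellipse(ellipse_histogram(2, 1, phi = 0))
  expect_equal(res$order_parameter, 2, tolerance = 0.05 * 2)
  expect_lt(min(res$major_axis_angle, 180 - res$major_axis_angle), 2)
  expect_equal(res$order_parameter, res$major_axis / res$minor_axis,
               tolerance = 1e-12)

  # ratio recovery across 1-4 at random orientations
  set.seed(11)
  for (ratio in c(1.3, 2, 3, 4)) {
    phi <- runif(1, 0, pi)
    r <- fit_ellipse(ellipse_histogram(ratio, 1, phi = phi))
    expect_equal(r$order_parameter, ratio, tolerance = 0.05 * ratio)
    dang <- abs((r$major_axis_angle - phi * 180 / pi + 90) %% 180 - 90)
    expect_lt(dang, 3)
  }

  # all weight in one antipodal bin pair: minor axis collapses
  w <- rep(0, 72); w[10] <- 1; w[46] <- 1
  ph <- ellipse_histogram(1, 1); ph$weights <- w
  expect_pg_error(fit_ellipse(ph), "pgafm_degenerate_error")

  # single nonzero bin likewise collapses
  w1 <- rep(0, 72); w1[3] <- 2
  ph$weights <- w1
  expect_pg_error(fit_ellipse(ph), "pgafm_degenerate_error")
})

test_that("order_parameter behaves across alignment regimes", {
  # perfectly aligned, noiseless features are strongly ordered
  sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                             n_features = 150,
                                             mean_angle = 0, angle_sd = 0,
                                             tip_sigma = 0, scanline_sd = 0,
                                             noise_sd = 0, seed = 2))
  expect_gt(order_parameter(sim$heightmap)$order_parameter, 2)

  expect_pg_error(order_parameter(heightmap(matrix(1, 64, 64), 1)),
                  "pgafm_degenerate_error")

  # order parameter is a ratio >= 1 by construction
  for (seed in 1:3) {
    s <- simulate_image(synthetic_image_spec(size = c(128, 128),
                                             n_features = 80,
                                             angle_dist = "uniform",
                                             seed = seed))
    expect_gte(order_parameter(s$heightmap)$order_parameter, 1)
  }
})

test_that("rotating an image by 90 degrees rotates the recovered axis, not the order", {
  sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                             n_features = 300,
                                             mean_angle = 30, angle_sd = 5,
                                             scanline_sd = 0, seed = 6))
  r1 <- order_parameter(sim$heightmap)
  rot <- heightmap(rotate90(sim$heightmap$heights), sim$heightmap$pixel_size)
  r2 <- order_parameter(rot)
  expect_equal(r2$order_parameter, r1$order_parameter,
               tolerance = 0.05 * r1$order_parameter)
  dang <- abs((r2$major_axis_angle - r1$major_axis_angle) %% 180 - 90)
  expect_lt(min(dang, abs(dang - 180)), 5)
})

test_that("order_map tiles the image and summarises local order", {
  # dense homogeneous image so every tile samples many orientations
  sim <- simulate_image(synthetic_image_spec(n_features = 6000,
                                             angle_dist = "uniform", seed = 5))
  om <- order_map(sim$heightmap, 4, 4)
  expect_equal(dim(om$values), c(4L, 4L))
  expect_length(om$results, 16L)
  expect_lt(om$sd, 0.2)                   # homogeneous by construction
  expect_equal(om$mean, mean(om$values))

  # a 1x1 map is the whole-image analysis
  om1 <- order_map(sim$heightmap, 1, 1, min_tile_px = 32L)
  expect_equal(om1$values[1, 1],
               order_parameter(sim$heightmap)$order_parameter)

  # ordered half vs isotropic half
  left <- simulate_image(synthetic_image_spec(size = c(512, 256),
                                              n_features = 400,
                                              mean_angle = 45, angle_sd = 5,
                                              seed = 8))
  right <- simulate_image(synthetic_image_spec(size = c(512, 256),
                                               n_features = 400,
                                               angle_dist = "uniform",
                                               seed = 9))
  combined <- heightmap(cbind(left$heightmap$heights, right$heightmap$heights),
                        2)
  om2 <- order_map(combined, 1, 2)
  expect_gt(om2$values[1, 1], om2$values[1, 2])

  expect_pg_error(order_map(sim$heightmap, 16, 16), "pgafm_size_error")
})

test_that("power_spectrum_anisotropy finds Fourier pairs and nothing in noise", {
  expect_equal(power_spectrum_anisotropy(heightmap(matrix(1, 64, 64), 1))$n_peaks,
               0L)

  z <- outer(seq_len(64), seq_len(64), function(y, x) sin(2 * pi * x / 8))
  sp <- power_spectrum_anisotropy(heightmap(z, 1))
  expect_equal(sp$n_peaks, 2L)
  expect_equal(sp$peaks$freq_cyc_per_nm, rep(1 / 8, 2L), tolerance = 1e-6)

  sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                             n_features = 300,
                                             angle_dist = "uniform", seed = 12))
  m <- downsample_half(subtract_plane(flatten_lines(sim$heightmap)))
  expect_equal(power_spectrum_anisotropy(m)$n_peaks, 0L)
})

test_that("compare_order contrasts groups with Welch and rank tests", {
  g <- c(1.1, 1.2, 1.3, 1.15)
  res <- compare_order(g, g)
  expect_false(res$significant)
  expect_gt(res$welch_p_value, 0.9)

  expect_pg_error(compare_order(c(1, 2), c(1, 2, 3)),
                  "pgafm_sample_size_error")

  aligned <- vapply(1:6, function(s) {
    sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                               n_features = 300, angle_sd = 5,
                                               seed = s))
    order_parameter(sim$heightmap)$order_parameter
  }, numeric(1))
  isotropic <- vapply(7:12, function(s) {
    sim <- simulate_image(synthetic_image_spec(size = c(256, 256),
                                               n_features = 300,
                                               angle_dist = "uniform",
                                               seed = s))
    order_parameter(sim$heightmap)$order_parameter
  }, numeric(1))
  res <- compare_order(aligned, isotropic)
  expect_true(res$significant)
  expect_lt(res$mann_whitney_p_value, 0.05)
})
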