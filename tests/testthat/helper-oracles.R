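# Independent oracles and fixture builders used across the suite.

# radius of an origin-centred ellipse (semi-axes a >= b, major axis rotated
# by phi) at polar angle theta
ellipse_radius <- function(theta, a, b, phi = 0) {
  t <- theta - phi
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

# polar_histogram whose bin radii lie exactly on that ellipse
ellipse_histogram <- function(a, b, phi = 0, n_bins = 72L) {
  th <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  structure(list(bin_edges = seq(0, 2 * pi, length.out = n_bins + 1L),
                 weights = ellipse_radius(th, a, b, phi),
                 n_pixels = n_bins, weighting = "magnitude",
                 min_magnitude = 0),
            class = "polar_histogram")
}

# gradient field built directly from vectors (bypasses differentiation)
make_gradient_field <- function(gx, gy, pixel_size = 1) {
  structure(list(gx = as.matrix(gx), gy = as.matrix(gy),
                 pixel_size = pixel_size),
            class = "gradient_field")
}

# brute-force local window mean with edge replication (oracle for the
# integral-image implementation)
brute_local_mean <- function(m, window) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-r:r), 1L), nr)
    jj <- pmin(pmax(j + (-r:r), 1L), nc)
    out[i, j] <- mean(m[ii, jj])
  }
  out
}

# rotate a matrix 90 degrees counter-clockwise
rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# dense numeric FWHM of a sampled curve (linear-interpolated crossings),
# independent of the package's fwhm()
dense_fwhm <- function(x, y) {
  ip <- which.max(y)
  half <- y[ip] / 2
  xl <- stats::approx(y[1:ip], x[1:ip], xout = half, ties = "ordered")$y
  n <- length(y)
  xr <- stats::approx(y[n:ip], x[n:ip], xout = half, ties = "ordered")$y
  xr - xl
}

# a small SEC calibration used by chromatogram fixtures
demo_calibration <- function() {
  calibrate_sec(data.frame(mw = 10^(7 - 0.5 * (2:6)), volume = 2:6))
}

expect_pg_error <- function(expr, class) {
  expect_error(expr, class = class)
}
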