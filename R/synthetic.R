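#' Specification of a synthetic AFM test image
#'
#' Parameterises the test-image simulator used to validate the orientation
#' pipeline: linear features (glycan-chain stand-ins) with random start
#' points, fixed length, and an angular orientation distribution of defined
#' mean and standard deviation (or uniform on \[0, 180)); Gaussian tip
#' convolution; per-scan-line offsets; per-pixel Gaussian noise.
#'
#' The defaults emulate a 1 micron, 512 x 512 scan of a dense chain network:
#' 800 features of 100 px (200 nm, the length scale of long glycan chains) at
#' 2 nm/px — roughly four-fold sparser than the ~2.7 nm chain spacing of real
#' sacculi images — 1.5 nm feature height, a 2 px (4 nm) Gaussian tip kernel,
#' and 0.1 nm scan-line and pixel noise typical of a low-noise AFM.
#'
#' @param size `c(rows, cols)` in pixels.
#' @param pixel_size nm per pixel.
#' @param n_features number of linear features.
#' @param feature_length feature length in pixels (fixed for all features).
#' @param mean_angle mean chain angle in degrees (x towards y/downwards).
#' @param angle_sd angular standard deviation in degrees (used when
#'   `angle_dist = "normal"`).
#' @param angle_dist `"normal"` or `"uniform"` (uniform on \[0, 180)).
#' @param feature_height feature height in nm (overlaps take the maximum,
#'   not the sum).
#' @param tip_sigma Gaussian tip kernel standard deviation in pixels
#'   (0 disables convolution).
#' @param scanline_sd standard deviation of per-row offsets in nm.
#' @param noise_sd standard deviation of i.i.d. per-pixel noise in nm.
#' @param seed integer RNG seed; a fixed seed reproduces the image exactly.
#' @return A list of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(size = c(512L, 512L), pixel_size = 2,
                                 n_features = 800L, feature_length = 100,
                                 mean_angle = 0, angle_sd = 5,
                                 angle_dist = c("normal", "uniform"),
                                 feature_height = 1.5, tip_sigma = 2,
                                 scanline_sd = 0.1, noise_sd = 0.1,
                                 seed = 1L) {
  angle_dist <- match.arg(angle_dist)
  if (n_features < 0L || feature_length < 1 || angle_sd < 0 ||
      tip_sigma < 0 || scanline_sd < 0 || noise_sd < 0)
    pg_stop("invalid simulator specification", "pgafm_spec_error")
  if (feature_length > sqrt(sum(as.numeric(size)^2)))
    pg_stop("feature length exceeds the image diagonal", "pgafm_spec_error")
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_features = as.integer(n_features),
                 feature_length = feature_length, mean_angle = mean_angle,
                 angle_sd = angle_sd, angle_dist = angle_dist,
                 feature_height = feature_height, tip_sigma = tip_sigma,
                 scanline_sd = scanline_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with whole-sample symmetric (reflective) padding;
# with a symmetric unit-sum kernel this preserves the image sum exactly
convolve_reflect <- function(m, kernel) {
  if (length(kernel) == 1L) return(m * kernel)
  r <- (length(kernel) - 1L) %/% 2L
  conv_cols <- function(mm) {
    n <- nrow(mm)
    if (r >= n)
      pg_stop("kernel larger than image", "pgafm_size_error")
    mp <- mm[c(r:1, seq_len(n), n:(n - r + 1L)), , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(kernel))
      out <- out + kernel[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Simulate a ground-truthed AFM test image
#'
#' Implements the four-stage simulator: (1) rasterise `n_features` segments
#' with uniformly random start points and angles drawn from the configured
#' distribution, painted at `feature_height` (overlaps take the maximum);
#' (2) convolve with a unit-sum Gaussian kernel of s.d. `tip_sigma`
#' (reflective borders, mass-preserving); (3) add a per-row offset drawn from
#' `N(0, scanline_sd)`; (4) add i.i.d. `N(0, noise_sd)` per pixel. The RNG is
#' seeded from `spec$seed` and consumed in a fixed order (start rows, start
#' columns, angles, row offsets, pixel noise) so the output is bit-identical
#' across runs.
#'
#' The intent is validation of the analysis pipeline on data with known
#' orientation statistics, not a physical model of the tip-sample interaction.
#'
#' @param spec a [synthetic_image_spec()].
#' @return A list with `heightmap` (a [heightmap()]) and `ground_truth`
#'   (list with a `features` data frame: `start_row`, `start_col`,
#'   `angle_deg`, and the `spec`).
#' @export
simulate_image <- function(spec) {
  if (!inherits(spec, "synthetic_image_spec"))
    pg_stop("expected a 'synthetic_image_spec'", "pgafm_spec_error")
  set.seed(spec$seed)
  nr <- spec$size[1L]; nc <- spec$size[2L]
  n <- spec$n_features
  r0 <- stats::runif(n, 1, nr)
  c0 <- stats::runif(n, 1, nc)
  ang <- if (spec$angle_dist == "uniform") {
    stats::runif(n, 0, 180)
  } else {
    (spec$mean_angle + stats::rnorm(n, 0, spec$angle_sd)) %% 180
  }
  img <- matrix(0, nr, nc)
  if (n > 0L) {
    tt <- seq(0, spec$feature_length, by = 0.25)
    for (i in seq_len(n)) {
      th <- ang[i] * pi / 180
      rr <- round(r0[i] + tt * sin(th))
      cc <- round(c0[i] + tt * cos(th))
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      if (!any(ok)) next
      idx <- cbind(rr[ok], cc[ok])
      img[idx] <- pmax(img[idx], spec$feature_height)
    }
  }
  img <- convolve_reflect(img, gaussian_kernel(spec$tip_sigma))
  img <- img + stats::rnorm(nr, 0, spec$scanline_sd)  # recycled down columns
  img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  list(heightmap = heightmap(img, spec$pixel_size,
                             sprintf("sim_seed%d", spec$seed)),
       ground_truth = list(features = data.frame(start_row = r0,
                                                 start_col = c0,
                                                 angle_deg = ang),
                           spec = spec))
}

#' Simulate a flat surface with square pore-like depressions
#'
#' A ground-truthed fixture for the pore segmentation: a flat surface minus
#' non-overlapping square depressions, with optional Gaussian pixel noise.
#'
#' @param size `c(rows, cols)` in pixels.
#' @param pixel_size nm per pixel.
#' @param depressions list of `list(origin = c(row, col), side = px,
#'   depth = nm)`; must lie inside the image and not overlap.
#' @param noise_sd per-pixel Gaussian noise in nm (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A list with `heightmap` and `ground_truth` (data frame with one
#'   row per depression: origin, side, depth, `pixel_area`, `area_nm2`).
#' @export
simulate_pore_image <- function(size, pixel_size, depressions = list(),
                                noise_sd = 0, seed = 1L) {
  nr <- size[1L]; nc <- size[2L]
  img <- matrix(0, nr, nc)
  occ <- matrix(FALSE, nr, nc)
  truth <- data.frame(origin_row = integer(0), origin_col = integer(0),
                      side_px = integer(0), depth_nm = numeric(0),
                      pixel_area = integer(0), area_nm2 = numeric(0))
  for (d in depressions) {
    r <- d$origin[1L]; c <- d$origin[2L]; s <- d$side
    if (r < 1L || c < 1L || r + s - 1L > nr || c + s - 1L > nc)
      pg_stop("depression extends outside the image", "pgafm_spec_error")
    rows <- r:(r + s - 1L); cols <- c:(c + s - 1L)
    if (any(occ[rows, cols]))
      pg_stop("depressions overlap", "pgafm_spec_error")
    occ[rows, cols] <- TRUE
    img[rows, cols] <- img[rows, cols] - d$depth
    truth[nrow(truth) + 1L, ] <- list(r, c, as.integer(s), d$depth,
                                      as.integer(s)^2,
                                      as.numeric(s)^2 * pixel_size^2)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  list(heightmap = heightmap(img, pixel_size, "sim_pores"),
       ground_truth = truth)
}

#' Simulate a size exclusion chromatogram with known mass fractions
#'
#' Gaussian elution peaks centred at the calibration-predicted elution
#' volumes of the given molecular weights, with areas proportional to the
#' mass fractions — a ground-truthed fixture for [fraction_before()].
#'
#' @param components data frame (or list of lists) with columns `mw` (Da),
#'   `fraction` (mass fractions summing to 1) and `width` (peak s.d. in
#'   volume units).
#' @param calibration a [calibrate_sec()] curve positioning the peaks.
#' @param n_points number of samples on the volume axis (default 2000).
#' @param noise_sd additive signal noise s.d. (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param volume_range optional `c(lo, hi)`; default spans all peaks +/- 5
#'   widths.
#' @return A list with `chromatogram` (a [chromatogram()]) and
#'   `ground_truth` (the component table with predicted elution volumes).
#' @export
simulate_chromatogram <- function(components, calibration, n_points = 2000L,
                                  noise_sd = 0, seed = 1L,
                                  volume_range = NULL) {
  if (!is.data.frame(components)) components <- do.call(rbind.data.frame, components)
  if (abs(sum(components$fraction) - 1) > 1e-6)
    pg_stop("component mass fractions must sum to 1", "pgafm_spec_error")
  vols <- vapply(components$mw, function(m) predict_volume(calibration, m),
                 numeric(1L))
  if (is.null(volume_range))
    volume_range <- c(min(vols - 5 * components$width),
                      max(vols + 5 * components$width))
  v <- seq(volume_range[1L], volume_range[2L], length.out = n_points)
  sig <- rep(0, n_points)
  for (i in seq_len(nrow(components))) {
    sig <- sig + components$fraction[i] *
      stats::dnorm(v, mean = vols[i], sd = components$width[i])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- pmax(sig + stats::rnorm(n_points, 0, noise_sd), 0)
  }
  truth <- components
  truth$elution_volume <- vols
  list(chromatogram = chromatogram(v, sig), ground_truth = truth)
}
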