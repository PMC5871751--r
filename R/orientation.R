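#' Numerical gradient of a height map
#'
#' Central differences in the interior, one-sided differences at the borders.
#' Units are nm of height per pixel; `gx` is the derivative along columns
#' (x), `gy` along rows (y, increasing downwards).
#'
#' @param hm a [heightmap()] of at least 3 x 3 pixels.
#' @return An object of class `gradient_field`: list with matrices `gx`, `gy`
#'   and the source `pixel_size`.
#' @export
gradient_field <- function(hm) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  nr <- nrow(h); nc <- ncol(h)
  if (nr < 3L || nc < 3L)
    pg_stop("gradient needs at least a 3 x 3 grid", "pgafm_size_error")
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (h[, 3:nc] - h[, 1:(nc - 2)]) / 2
  gx[, 1] <- h[, 2] - h[, 1]
  gx[, nc] <- h[, nc] - h[, nc - 1]
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (h[3:nr, ] - h[1:(nr - 2), ]) / 2
  gy[1, ] <- h[2, ] - h[1, ]
  gy[nr, ] <- h[nr, ] - h[nr - 1, ]
  structure(list(gx = gx, gy = gy, pixel_size = hm$pixel_size),
            class = "gradient_field")
}

#' Polar histogram of gradient orientations
#'
#' Each pixel whose gradient magnitude reaches `min_magnitude` contributes to
#' the angular bin containing `atan2(gy, gx)`; the contribution is the
#' magnitude (default) or 1. Bins uniformly cover \[0, 2pi). Because a ridge
#' produces gradients on both flanks, the histogram of a well-aligned image
#' shows two antipodal lobes perpendicular to the ridge direction.
#'
#' @param gf a [gradient_field()].
#' @param n_bins even number of bins, >= 8 (default 72, i.e. 5 degree bins).
#' @param weighting `"magnitude"` (default) or `"count"`.
#' @param min_magnitude minimum gradient magnitude (nm/px) for a pixel to
#'   contribute; default 0 (magnitude weighting already suppresses flat
#'   background).
#' @return An object of class `polar_histogram`: list with `bin_edges`
#'   (length `n_bins + 1`, radians), `weights`, `n_pixels` (contributing
#'   pixels) and the parameters used.
#' @export
orientation_histogram <- function(gf, n_bins = 72L,
                                  weighting = c("magnitude", "count"),
                                  min_magnitude = 0) {
  if (!inherits(gf, "gradient_field"))
    pg_stop("expected a 'gradient_field'", "pgafm_format_error")
  weighting <- match.arg(weighting)
  n_bins <- as.integer(n_bins)
  if (n_bins < 8L || n_bins %% 2L != 0L)
    pg_stop("'n_bins' must be an even integer >= 8", "pgafm_format_error")
  mag <- sqrt(gf$gx^2 + gf$gy^2)
  keep <- mag >= min_magnitude & mag > 0
  if (!any(keep))
    pg_stop("no pixel has gradient magnitude above 'min_magnitude' (degenerate input)",
            "pgafm_degenerate_error")
  ang <- atan2(gf$gy[keep], gf$gx[keep]) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1L, n_bins)
  w <- if (weighting == "magnitude") mag[keep] else rep(1, sum(keep))
  weights <- vapply(seq_len(n_bins),
                    function(i) sum(w[bin == i]), numeric(1L))
  structure(list(bin_edges = seq(0, 2 * pi, length.out = n_bins + 1L),
                 weights = weights, n_pixels = sum(keep),
                 weighting = weighting, min_magnitude = min_magnitude),
            class = "polar_histogram")
}

bin_centres <- function(ph) {
  n <- length(ph$weights)
  (seq_len(n) - 0.5) * 2 * pi / n
}

#' Fit an origin-centred ellipse to a polar histogram
#'
#' Each bin is treated as a point at radius = weight, angle = bin centre; the
#' set is symmetrised by adding antipodal counterparts (chain orientation is
#' an axis, not a direction). The generating ellipse is recovered from the
#' second-moment tensor of the points: for points uniform in polar angle on an
#' ellipse with semi-axes `a >= b`, the eigenvalues of the second-moment
#' tensor are `l1 = a^2 b/(a+b)` and `l2 = a b^2/(a+b)`, so
#' `a = sqrt((l1+l2) l1/l2)`, `b = sqrt((l1+l2) l2/l1)` and the axis ratio is
#' `a/b = l1/l2`. The fit is closed-form, deterministic, and exact when the
#' bin radii lie on an ellipse.
#'
#' The **orientational order parameter** is the ratio of the long to the short
#' axis of this ellipse: 1 for an isotropic histogram, larger for aligned
#' images. Because gradients are perpendicular to ridge lines, the estimated
#' chain direction is `major_axis_angle + 90` (reported as `chain_angle`).
#'
#' @param ph a [orientation_histogram()] result.
#' @return An object of class `orientation_result`: list with
#'   `order_parameter` (>= 1), `major_axis`, `minor_axis`, `major_axis_angle`
#'   (degrees in \[0, 180)), `chain_angle` (degrees in \[0, 180)) and
#'   `n_pixels`.
#' @export
fit_ellipse <- function(ph) {
  if (!inherits(ph, "polar_histogram"))
    pg_stop("expected a 'polar_histogram'", "pgafm_format_error")
  w <- ph$weights
  if (any(w < 0) || sum(w) <= 0)
    pg_stop("histogram weights must be non-negative with positive total",
            "pgafm_degenerate_error")
  th <- bin_centres(ph)
  x <- c(w * cos(th), -w * cos(th))
  y <- c(w * sin(th), -w * sin(th))
  S <- matrix(c(mean(x * x), mean(x * y), mean(x * y), mean(y * y)), 2L, 2L)
  e <- eigen(S, symmetric = TRUE)
  l1 <- e$values[1L]; l2 <- e$values[2L]
  if (l2 <= l1 * 1e-12)
    pg_stop("histogram collapses onto a single axis: minor axis is zero",
            "pgafm_degenerate_error")
  nz <- sum(w > 0)
  if (nz < 3L) {
    # a lone antipodal pair is rank-1 and caught above; any other < 3 bins
    # cannot constrain an ellipse
    pg_stop("fewer than 3 nonzero bins: cannot fit an ellipse", "pgafm_fit_error")
  }
  a <- sqrt((l1 + l2) * l1 / l2)
  b <- sqrt((l1 + l2) * l2 / l1)
  ang <- (atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]) * 180 / pi) %% 180
  structure(list(order_parameter = l1 / l2, major_axis = a, minor_axis = b,
                 major_axis_angle = ang, chain_angle = (ang + 90) %% 180,
                 n_pixels = if (is.null(ph$n_pixels)) NA_integer_ else ph$n_pixels),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf(paste0("<orientation_result> order parameter %.3f ",
                     "(axes %.3g/%.3g), gradient major axis %.1f deg, ",
                     "chain direction %.1f deg, n = %s px\n"),
              x$order_parameter, x$major_axis, x$minor_axis,
              x$major_axis_angle, x$chain_angle, format(x$n_pixels)))
  invisible(x)
}

#' Configuration for the orientational order pipeline
#'
#' @param flatten_degree per-row polynomial degree for [flatten_lines()].
#' @param downsample logical; average 2x2 blocks before differentiation.
#' @param n_bins,weighting,min_magnitude passed to [orientation_histogram()].
#' @return A list of class `order_config`.
#' @export
order_config <- function(flatten_degree = 0L, downsample = TRUE, n_bins = 72L,
                         weighting = "magnitude", min_magnitude = 0) {
  structure(list(flatten_degree = as.integer(flatten_degree),
                 downsample = isTRUE(downsample), n_bins = as.integer(n_bins),
                 weighting = weighting, min_magnitude = min_magnitude),
            class = "order_config")
}

#' Orientational order parameter of a height map
#'
#' Runs the full analysis chain on one image: line flattening, plane
#' subtraction, 0.5x downsampling, numerical gradient, polar histogram of
#' gradient orientations, ellipse fit. The result's `order_parameter` is ~1
#' for images with isotropically oriented features and grows with alignment.
#'
#' @param hm a [heightmap()].
#' @param cfg an [order_config()].
#' @return An `orientation_result` (see [fit_ellipse()]).
#' @examples
#' sim <- simulate_image(synthetic_image_spec(size = c(128, 128),
#'                                            n_features = 60, seed = 1))
#' order_parameter(sim$heightmap)
#' @export
order_parameter <- function(hm, cfg = order_config()) {
  hm <- as_heightmap(hm)
  m <- subtract_plane(flatten_lines(hm, cfg$flatten_degree))
  if (cfg$downsample) m <- downsample_half(m)
  ph <- orientation_histogram(gradient_field(m), n_bins = cfg$n_bins,
                              weighting = cfg$weighting,
                              min_magnitude = cfg$min_magnitude)
  fit_ellipse(ph)
}

#' Map of local orientational order
#'
#' Tiles the image into `n_rows` x `n_cols` non-overlapping sub-regions and
#' computes the order parameter independently in each, yielding a spatial map
#' of local alignment together with its mean and standard deviation.
#'
#' @param hm a [heightmap()].
#' @param n_rows,n_cols tiling (default 4 x 4 = 16 sub-regions).
#' @param cfg an [order_config()].
#' @param min_tile_px minimum tile side, in pixels, after downsampling.
#' @return An object of class `order_map`: list with `values` (matrix of
#'   order parameters), `results` (list of `orientation_result`), `tiles`
#'   (data frame of pixel extents), `mean`, `sd`.
#' @export
order_map <- function(hm, n_rows = 4L, n_cols = 4L, cfg = order_config(),
                      min_tile_px = 32L) {
  hm <- as_heightmap(hm)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  h <- hm$heights
  rb <- floor(seq(0L, nrow(h), length.out = n_rows + 1L))
  cb <- floor(seq(0L, ncol(h), length.out = n_cols + 1L))
  div <- if (cfg$downsample) 2L else 1L
  if (min(diff(rb)) %/% div < min_tile_px || min(diff(cb)) %/% div < min_tile_px)
    pg_stop(sprintf("tiles smaller than %d px after downsampling", min_tile_px),
            "pgafm_size_error")
  vals <- matrix(NA_real_, n_rows, n_cols)
  results <- vector("list", n_rows * n_cols)
  tiles <- data.frame(tile_row = integer(0), tile_col = integer(0),
                      row_from = integer(0), row_to = integer(0),
                      col_from = integer(0), col_to = integer(0))
  k <- 0L
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    k <- k + 1L
    rows <- (rb[i] + 1L):rb[i + 1L]; cols <- (cb[j] + 1L):cb[j + 1L]
    sub <- heightmap(h[rows, cols, drop = FALSE], hm$pixel_size,
                     sprintf("%s[tile %d,%d]", hm$name, i, j))
    res <- order_parameter(sub, cfg)
    vals[i, j] <- res$order_parameter
    results[[k]] <- res
    tiles[k, ] <- list(i, j, rb[i] + 1L, rb[i + 1L], cb[j] + 1L, cb[j + 1L])
  }
  structure(list(values = vals, results = results, tiles = tiles,
                 mean = mean(vals), sd = stats::sd(as.vector(vals))),
            class = "order_map")
}

#' @export
print.order_map <- function(x, ...) {
  cat(sprintf("<order_map> %d x %d sub-regions, mean order parameter %.3f (s.d. %.3f)\n",
              nrow(x$values), ncol(x$values), x$mean, x$sd))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.data.frame.order_map <- function(x, ...) {
  df <- x$tiles
  df$order_parameter <- mapply(function(i, j) x$values[i, j],
                               df$tile_row, df$tile_col)
  df$chain_angle <- vapply(seq_len(nrow(df)), function(k)
    x$results[[k]]$chain_angle, numeric(1L))
  df
}

#' Spectral anisotropy of a height map
#'
#' A cross-check on real-space order: the windowed 2D power spectrum of an
#' image with no long-range periodic chain spacing shows no discrete spots,
#' but partial alignment elongates the central lobe. The magnitude spectrum
#' is lightly smoothed (5x5 box) to suppress single-pixel speckle, and peaks
#' are strict local maxima exceeding the radially matched (annulus)
#' background mean by 5 standard deviations, both estimated robustly (median
#' and scaled MAD, so genuine spots cannot inflate their own background),
#' excluding the DC component and its shoulder. The central-lobe axis ratio
#' is the second-moment axis ratio of the magnitude within the half-maximum
#' region around DC.
#'
#' @param hm a [heightmap()] of at least 64 x 64 pixels.
#' @param n_sd peak threshold in background standard deviations (default 5).
#' @return List of class `spectrum_record`: `peaks` (data frame: row, col,
#'   spatial frequency cycles/nm, magnitude), `n_peaks`, `central_lobe_ratio`.
#' @export
power_spectrum_anisotropy <- function(hm, n_sd = 5) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  nr <- nrow(h); nc <- ncol(h)
  if (nr < 64L || nc < 64L)
    pg_stop("spectrum needs at least 64 x 64 pixels", "pgafm_size_error")
  h <- h - mean(h)
  wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))  # Hann
  wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  mag <- Mod(stats::fft(h * outer(wr, wc)))
  # centre DC
  mag <- mag[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
  mag <- box_smooth(mag, 2L)
  r0 <- nr %/% 2 + 1L; c0 <- nc %/% 2 + 1L
  fy <- (row(mag) - r0) / nr; fx <- (col(mag) - c0) / nc  # cycles per pixel
  rad <- sqrt((row(mag) - r0)^2 + (col(mag) - c0)^2)
  ann <- pmax(1L, round(rad))
  thr <- matrix(Inf, nr, nc)
  for (a in sort(unique(as.vector(ann)))) {
    v <- mag[ann == a]
    # robust background: median and MAD-scaled s.d.
    thr[ann == a] <- stats::median(v) +
      n_sd * 1.4826 * stats::mad(v, constant = 1)
  }
  # strict local maxima over the 8-neighbourhood
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  centre <- mag[inner_r, inner_c]
  is_max <- matrix(TRUE, nr - 2L, nc - 2L)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & centre > mag[inner_r + dr, inner_c + dc]
  }
  cand <- matrix(FALSE, nr, nc)
  cand[inner_r, inner_c] <- is_max
  cand <- cand & (mag > thr) & (rad > 2)  # exclude DC and its shoulder
  idx <- which(cand, arr.ind = TRUE)
  peaks <- data.frame(row = idx[, 1L], col = idx[, 2L],
                      freq_cyc_per_nm = sqrt(fx[idx]^2 + fy[idx]^2) / hm$pixel_size,
                      magnitude = mag[idx])
  peaks <- peaks[order(-peaks$magnitude), , drop = FALSE]
  # central lobe: half-maximum region around DC
  lobe <- mag >= max(mag) / 2 & rad <= min(nr, nc) / 4
  ratio <- NA_real_
  if (sum(lobe) >= 3L && stats::sd(mag[lobe]) > 0) {
    wgt <- mag[lobe]
    xs <- (col(mag)[lobe] - c0); ys <- (row(mag)[lobe] - r0)
    S <- matrix(c(sum(wgt * xs * xs), sum(wgt * xs * ys),
                  sum(wgt * xs * ys), sum(wgt * ys * ys)), 2L, 2L) / sum(wgt)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ratio <- if (ev[2L] > 0) sqrt(ev[1L] / ev[2L]) else NA_real_
  } else if (sum(lobe) <= 1L) {
    ratio <- 1
  }
  structure(list(peaks = peaks, n_peaks = nrow(peaks),
                 central_lobe_ratio = ratio),
            class = "spectrum_record")
}

# mean over a (2r+1)^2 box with edge replication
box_smooth <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[pmin(pmax(seq(1L - r, nr + r), 1L), nr),
         pmin(pmax(seq(1L - r, nc + r), 1L), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in 0:(2L * r)) for (dc in 0:(2L * r))
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  out / (2 * r + 1)^2
}

#' Compare orientational order between two groups of images
#'
#' Two-sided Welch two-sample t-test on the order parameters, with the
#' Mann-Whitney (Wilcoxon rank-sum) test reported alongside for small
#' samples.
#'
#' @param group_a,group_b numeric vectors of order parameters, each n >= 3.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return List of class `order_comparison`: Welch statistic and p-value,
#'   Mann-Whitney statistic and p-value, group means and sizes, and
#'   `significant` (Welch p < alpha).
#' @export
compare_order <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    pg_stop("each group needs at least 3 order parameters",
            "pgafm_sample_size_error")
  tt <- stats::t.test(group_a, group_b)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  structure(list(welch_statistic = unname(tt$statistic),
                 welch_p_value = tt$p.value,
                 mann_whitney_statistic = unname(wt$statistic),
                 mann_whitney_p_value = wt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b),
                 alpha = alpha, significant = tt$p.value < alpha),
            class = "order_comparison")
}
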