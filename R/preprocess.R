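#' Line-flatten a height map
#'
#' Raster-scanned probe images carry row-wise offsets ("scan-line noise").
#' Line flattening removes, from each row independently, the least-squares
#' polynomial of the given degree fitted to that row. The default degree 0
#' subtracts the row mean, the minimal correction for per-line offsets;
#' degree 1 additionally removes per-row tilt.
#'
#' The operation is a projection: applying it twice equals applying it once.
#'
#' @param hm a [heightmap()].
#' @param degree polynomial degree per row, integer >= 0 (default 0).
#' @return The flattened [heightmap()] (same shape and pixel size).
#' @export
flatten_lines <- function(hm, degree = 0L) {
  hm <- as_heightmap(hm)
  degree <- as.integer(degree)
  if (degree < 0L) pg_stop("'degree' must be >= 0", "pgafm_fit_error")
  h <- hm$heights
  nc <- ncol(h)
  if (degree >= nc)
    pg_stop("polynomial degree must be smaller than the row length",
            "pgafm_fit_error")
  if (degree == 0L) {
    res <- h - rowMeans(h)
  } else {
    x <- seq_len(nc)
    X <- stats::poly(x, degree = degree, raw = FALSE)
    X <- cbind(1, X)
    # one QR for all rows: residuals of t(h) regressed on the row basis
    fit <- stats::lm.fit(X, t(h))
    res <- t(fit$residuals)
  }
  heightmap(res, hm$pixel_size, hm$name)
}

#' Subtract the least-squares plane
#'
#' Fits `z = a + b*x + c*y` (x = column, y = row index) to all pixels by least
#' squares and subtracts it, removing sample tilt. Refitting the output
#' returns coefficients at numerical zero.
#'
#' @param hm a [heightmap()].
#' @return The levelled [heightmap()].
#' @export
subtract_plane <- function(hm) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  if (length(h) < 3L || nrow(h) < 2L || ncol(h) < 2L)
    pg_stop("plane fit needs at least a 2 x 2 grid", "pgafm_fit_error")
  x <- as.vector(col(h)); y <- as.vector(row(h))
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(h))
  heightmap(matrix(fit$residuals, nrow(h), ncol(h)), hm$pixel_size, hm$name)
}

#' Downsample by averaging 2x2 pixel blocks
#'
#' Non-overlapping 2x2 blocks of the parent image are averaged to single
#' pixels (0.5-fold downsampling), which suppresses residual scan-line noise
#' before gradient analysis. A trailing odd row or column is cropped so that
#' every output pixel is an exact four-pixel mean; the pixel size doubles.
#'
#' @param hm a [heightmap()] of at least 2 x 2 pixels.
#' @return The downsampled [heightmap()].
#' @export
downsample_half <- function(hm) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  if (nrow(h) < 2L || ncol(h) < 2L)
    pg_stop("downsampling needs at least a 2 x 2 grid", "pgafm_size_error")
  nr <- 2L * (nrow(h) %/% 2L); nc <- 2L * (ncol(h) %/% 2L)
  h <- h[seq_len(nr), seq_len(nc), drop = FALSE]
  ro <- seq(1L, nr, 2L); co <- seq(1L, nc, 2L)
  out <- 0.25 * (h[ro, co, drop = FALSE] + h[ro + 1L, co, drop = FALSE] +
                 h[ro, co + 1L, drop = FALSE] + h[ro + 1L, co + 1L, drop = FALSE])
  heightmap(out, 2 * hm$pixel_size, hm$name)
}
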