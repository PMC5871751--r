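#' Extract an interpolated line profile
#'
#' Samples the height map along the segment from `p0` to `p1` by bilinear
#' interpolation; the distance axis is in nm via the pixel size. Used to
#' measure chain cross-sections (width, inter-chain spacing).
#'
#' @param hm a [heightmap()].
#' @param p0,p1 endpoints as `c(row, col)` (may be fractional), inside the
#'   image.
#' @param n_samples number of samples; default one per half pixel of segment
#'   length (minimum 2), or a single sample for a zero-length segment.
#' @return A data frame of class `line_profile` with columns `distance_nm`
#'   and `height_nm`; attributes `pixel_size`, `p0`, `p1`.
#' @export
extract_profile <- function(hm, p0, p1, n_samples = NULL) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  chk <- function(p) {
    if (length(p) != 2L || p[1L] < 1 || p[1L] > nrow(h) ||
        p[2L] < 1 || p[2L] > ncol(h))
      pg_stop("profile endpoints must lie inside the image", "pgafm_bounds_error")
  }
  chk(p0); chk(p1)
  len_px <- sqrt(sum((p1 - p0)^2))
  if (is.null(n_samples))
    n_samples <- if (len_px == 0) 1L else max(2L, ceiling(2 * len_px) + 1L)
  t <- if (n_samples == 1L) 0 else seq(0, 1, length.out = n_samples)
  rr <- p0[1L] + t * (p1[1L] - p0[1L])
  cc <- p0[2L] + t * (p1[2L] - p0[2L])
  r0 <- pmin(floor(rr), nrow(h) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cc), ncol(h) - 1L); c0 <- pmax(c0, 1L)
  fr <- rr - r0; fc <- cc - c0
  if (nrow(h) == 1L) { r0 <- rep(1L, length(rr)); fr <- fr * 0 }
  if (ncol(h) == 1L) { c0 <- rep(1L, length(cc)); fc <- fc * 0 }
  v <- h[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       h[cbind(pmin(r0 + 1L, nrow(h)), c0)] * fr * (1 - fc) +
       h[cbind(r0, pmin(c0 + 1L, ncol(h)))] * (1 - fr) * fc +
       h[cbind(pmin(r0 + 1L, nrow(h)), pmin(c0 + 1L, ncol(h)))] * fr * fc
  out <- data.frame(distance_nm = t * len_px * hm$pixel_size, height_nm = v)
  structure(out, class = c("line_profile", "data.frame"),
            pixel_size = hm$pixel_size, p0 = p0, p1 = p1)
}

as_profile <- function(profile) {
  if (is.data.frame(profile) &&
      all(c("distance_nm", "height_nm") %in% names(profile)))
    return(profile)
  if (is.list(profile) && !is.null(profile$distance_nm))
    return(data.frame(distance_nm = profile$distance_nm,
                      height_nm = profile$height_nm))
  pg_stop("expected a profile with 'distance_nm' and 'height_nm'",
          "pgafm_format_error")
}

#' Full width at half maximum of a profile peak
#'
#' Locates the dominant maximum, references the half-maximum level to a
#' baseline — by default the mean of the local minima flanking the peak
#' (falling back to the profile end points), alternatively the global
#' minimum — and finds the two half-level crossings by linear interpolation.
#' For a Gaussian peak of standard deviation `sigma` on a flat baseline the
#' width is `2*sqrt(2*log(2))*sigma ≈ 2.3548*sigma`.
#'
#' @param profile a [extract_profile()] result or data frame with
#'   `distance_nm`, `height_nm`.
#' @param baseline `"local_minima"` (default) or `"global_min"`.
#' @return Width in nm, with attributes `peak_position_nm`, `half_level_nm`.
#' @export
fwhm <- function(profile, baseline = c("local_minima", "global_min")) {
  baseline <- match.arg(baseline)
  pr <- as_profile(profile)
  d <- pr$distance_nm; z <- pr$height_nm
  n <- length(z)
  if (n < 3L) pg_stop("profile too short for a peak", "pgafm_no_peak_error")
  ip <- which.max(z)
  base <- if (baseline == "global_min") {
    min(z)
  } else {
    left <- local_min_before(z, ip)
    right <- local_min_after(z, ip)
    mean(c(left, right))
  }
  if (z[ip] <= base)
    pg_stop("no peak above the baseline", "pgafm_no_peak_error")
  half <- base + (z[ip] - base) / 2
  xl <- cross_down(d, z, ip, half, dir = -1L)
  xr <- cross_down(d, z, ip, half, dir = +1L)
  if (is.na(xl) || is.na(xr))
    pg_stop("peak does not fall to half maximum on both sides",
            "pgafm_no_peak_error")
  structure(xr - xl, peak_position_nm = d[ip], half_level_nm = half)
}

local_min_before <- function(z, ip) {
  if (ip <= 2L) return(z[1L])
  for (i in (ip - 1L):2L)
    if (z[i] <= z[i - 1L] && z[i] <= z[i + 1L]) return(z[i])
  z[1L]
}

local_min_after <- function(z, ip) {
  n <- length(z)
  if (ip >= n - 1L) return(z[n])
  for (i in (ip + 1L):(n - 1L))
    if (z[i] <= z[i - 1L] && z[i] <= z[i + 1L]) return(z[i])
  z[n]
}

# first crossing of 'level' walking from peak ip in direction dir
cross_down <- function(d, z, ip, level, dir) {
  i <- ip
  n <- length(z)
  while (i + dir >= 1L && i + dir <= n) {
    j <- i + dir
    if (z[j] <= level) {
      f <- (z[i] - level) / (z[i] - z[j])
      return(d[i] + f * (d[j] - d[i]))
    }
    i <- j
  }
  NA_real_
}

#' Spacings between consecutive profile peaks
#'
#' Finds local maxima with topographic prominence of at least
#' `min_prominence`, refines each position by a parabolic fit through the
#' three samples around the maximum (sub-sample accuracy matters because
#' nanometre spacings span few pixels), and returns the spacings between
#' consecutive peaks.
#'
#' @param profile a profile (see [fwhm()]).
#' @param min_prominence minimum peak prominence in nm (default 0).
#' @return Numeric vector of spacings in nm, with attribute
#'   `peak_positions_nm`.
#' @export
peak_spacing <- function(profile, min_prominence = 0) {
  pr <- as_profile(profile)
  d <- pr$distance_nm; z <- pr$height_nm
  n <- length(z)
  if (n < 3L)
    pg_stop("need at least two resolvable peaks", "pgafm_insufficient_peaks_error")
  cand <- which(z[2:(n - 1L)] > z[1:(n - 2L)] & z[2:(n - 1L)] >= z[3:n]) + 1L
  keep <- cand[vapply(cand, function(i) prominence(z, i) >= min_prominence,
                      logical(1L))]
  if (length(keep) < 2L)
    pg_stop("fewer than two peaks above the prominence threshold",
            "pgafm_insufficient_peaks_error")
  pos <- vapply(keep, function(i) {
    if (i <= 1L || i >= n) return(d[i])
    y1 <- z[i - 1L]; y2 <- z[i]; y3 <- z[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 0.5), -0.5)
    d[i] + delta * (d[min(i + 1L, n)] - d[max(i - 1L, 1L)]) / 2
  }, numeric(1L))
  structure(diff(pos), peak_positions_nm = pos)
}

# topographic prominence: height of peak i above its lowest contour line.
# Each side's base is the minimum between the peak and the next higher sample
# (or the signal end); the prominence is the drop to the higher of the two.
prominence <- function(z, i) {
  n <- length(z)
  j <- i - 1L; lm <- z[i]
  while (j >= 1L && z[j] <= z[i]) { lm <- min(lm, z[j]); j <- j - 1L }
  j <- i + 1L; rm <- z[i]
  while (j <= n && z[j] <= z[i]) { rm <- min(rm, z[j]); j <- j + 1L }
  z[i] - max(lm, rm)
}
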