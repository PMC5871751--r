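#' Bradley adaptive threshold for pore candidates
#'
#' Adaptive binarisation comparing every pixel with the mean of its local
#' `window` x `window` neighbourhood, computed in O(1) per pixel with an
#' integral image over an edge-replicated padding. The image is first shifted
#' and rescaled to \[0, 1\]; a pixel is marked as a pore candidate when its
#' value falls below `local_mean * (1 - sensitivity)` — the dark-object
#' convention, since pores are depressions in a height map.
#'
#' @param hm a [heightmap()].
#' @param window odd window side in pixels, >= 3; default
#'   `image width %/% 8` rounded to odd.
#' @param sensitivity fraction in (0, 1); larger values mark fewer pixels.
#' @return A logical matrix (`TRUE` = pore candidate) with attribute
#'   `pixel_size`.
#' @export
bradley_threshold <- function(hm, window = NULL, sensitivity = 0.15) {
  hm <- as_heightmap(hm)
  h <- hm$heights
  if (is.null(window)) window <- odd_window(ncol(h) %/% 8L)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    pg_stop("'window' must be an odd integer >= 3", "pgafm_size_error")
  if (window > nrow(h) || window > ncol(h))
    pg_stop("'window' is larger than the image", "pgafm_size_error")
  if (!is.numeric(sensitivity) || sensitivity <= 0 || sensitivity >= 1)
    pg_stop("'sensitivity' must lie in (0, 1)", "pgafm_format_error")
  rng <- max(h) - min(h)
  norm <- if (rng > 0) (h - min(h)) / rng else h * 0
  mask <- norm < local_mean(norm, window) * (1 - sensitivity)
  attr(mask, "pixel_size") <- hm$pixel_size
  mask
}

odd_window <- function(w) max(3L, as.integer(w) %/% 2L * 2L + 1L)

# local window mean via integral image on an edge-replicated pad
local_mean <- function(m, window) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)),
           c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  # integral image with a zero first row/column
  ii <- rbind(0, cbind(0, t(apply(apply(pad, 2L, cumsum), 1L, cumsum))))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  i2 <- i1 + 2L * r; j2 <- j1 + 2L * r
  (ii[i2 + 1L, j2 + 1L] - ii[i1, j2 + 1L] - ii[i2 + 1L, j1] + ii[i1, j1]) /
    (window * window)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged with a union-find pass over the adjacency pairs.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]   # NW-SE diagonal neighbours
  c_ <- lab[-nr, -1L]; d <- lab[-1L, -nc]  # NE-SW diagonal neighbours
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Remove small connected components from a binary mask
#'
#' Drops every 8-connected foreground component of `min_pixels - 1` pixels or
#' fewer; the default keeps components of at least 5 pixels, setting the
#' minimum definition of a pore ("regions of four or less pixels" removed).
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_pixels smallest component size kept (default 5).
#' @return Logical matrix with the small components removed.
#' @export
filter_small_components <- function(mask, min_pixels = 5L) {
  mask <- mask > 0
  lab <- label_components_8(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_pixels)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Detect pores in a height map
#'
#' The segmentation chain of the pore analysis: Bradley adaptive threshold
#' ([bradley_threshold()]), morphological hole filling, removal of components
#' of four or fewer pixels ([filter_small_components()]), and 8-connected
#' labelling of the surviving components as pores with areas in nm².
#' The result is invariant to adding a constant to all heights.
#'
#' @inheritParams bradley_threshold
#' @param min_pixels smallest pixel count that counts as a pore (default 5).
#' @return An object of class `pore_set`: list with `pores` (data frame:
#'   `pore_id`, `pixel_count`, `area_nm2`, `centroid_row`, `centroid_col`),
#'   `mask` (logical matrix), `pixel_size`, and the parameters used.
#' @examples
#' sim <- simulate_pore_image(c(64, 64), pixel_size = 1,
#'   depressions = list(list(origin = c(10, 10), side = 5, depth = 2)), seed = 1)
#' detect_pores(sim$heightmap, window = 15, sensitivity = 0.2)$pores
#' @export
detect_pores <- function(hm, window = NULL, sensitivity = 0.15,
                         min_pixels = 5L) {
  hm <- as_heightmap(hm)
  cand <- bradley_threshold(hm, window, sensitivity)
  filled <- EBImage::fillHull(cand * 1) > 0
  kept <- filter_small_components(filled, min_pixels)
  lab <- label_components_8(kept)
  n <- max(lab)
  if (n == 0L) {
    pores <- data.frame(pore_id = integer(0), pixel_count = integer(0),
                        area_nm2 = numeric(0), centroid_row = numeric(0),
                        centroid_col = numeric(0))
  } else {
    px <- which(lab > 0L, arr.ind = TRUE)
    id <- lab[lab > 0L]
    count <- tabulate(id, nbins = n)
    pores <- data.frame(
      pore_id = seq_len(n),
      pixel_count = count,
      area_nm2 = count * hm$pixel_size^2,
      centroid_row = as.vector(tapply(px[, 1L], id, mean)),
      centroid_col = as.vector(tapply(px[, 2L], id, mean)))
  }
  structure(list(pores = pores, mask = kept, pixel_size = hm$pixel_size,
                 window = if (is.null(window)) odd_window(ncol(hm$heights) %/% 8L)
                          else as.integer(window),
                 sensitivity = sensitivity, min_pixels = as.integer(min_pixels)),
            class = "pore_set")
}

#' @export
print.pore_set <- function(x, ...) {
  cat(sprintf("<pore_set> %d pores (window %d px, sensitivity %.2f, >= %d px each)\n",
              nrow(x$pores), x$window, x$sensitivity, x$min_pixels))
  if (nrow(x$pores) > 0L)
    cat(sprintf("  areas %.3g-%.3g nm2\n", min(x$pores$area_nm2),
                max(x$pores$area_nm2)))
  invisible(x)
}

#' @export
as.data.frame.pore_set <- function(x, ...) x$pores

#' Summary statistics of a pore set
#'
#' @param ps a [detect_pores()] result.
#' @param small_area_nm2 area threshold for the reported "small pore"
#'   fraction (default 5 nm²).
#' @param hist_breaks number of bins for the area histogram.
#' @return List of class `pore_summary`: `count`, `max_area_nm2` (NA and
#'   flagged when the set is empty), `mean_area_nm2`, area quantiles,
#'   `fraction_below` (pores with area < `small_area_nm2`), and an area
#'   histogram (`breaks`, `counts`).
#' @export
pore_stats <- function(ps, small_area_nm2 = 5, hist_breaks = 10L) {
  if (!inherits(ps, "pore_set"))
    pg_stop("expected a 'pore_set'", "pgafm_format_error")
  a <- ps$pores$area_nm2
  if (length(a) == 0L) {
    return(structure(list(count = 0L, max_area_nm2 = NA_real_, empty = TRUE,
                          mean_area_nm2 = NA_real_, quantiles_nm2 = NULL,
                          small_area_nm2 = small_area_nm2,
                          fraction_below = NA_real_, histogram = NULL),
                     class = "pore_summary"))
  }
  hs <- graphics::hist(a, breaks = hist_breaks, plot = FALSE)
  structure(list(count = length(a), max_area_nm2 = max(a), empty = FALSE,
                 mean_area_nm2 = mean(a),
                 quantiles_nm2 = stats::quantile(a, c(0.25, 0.5, 0.75, 0.95)),
                 small_area_nm2 = small_area_nm2,
                 fraction_below = mean(a < small_area_nm2),
                 histogram = list(breaks = hs$breaks, counts = hs$counts)),
            class = "pore_summary")
}

#' @export
print.pore_summary <- function(x, ...) {
  if (x$empty) {
    cat("<pore_summary> no pores\n")
  } else {
    cat(sprintf("<pore_summary> %d pores, max %.3g nm2, %.0f%% below %.3g nm2\n",
                x$count, x$max_area_nm2, 100 * x$fraction_below,
                x$small_area_nm2))
  }
  invisible(x)
}
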