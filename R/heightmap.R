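#' Construct an AFM height map
#'
#' The universal image container of the package: a rectangular grid of heights
#' in nanometres with an isotropic pixel size. Row 1 is the top of the image;
#' `x` is the column index and `y` the row index, so the fast scan axis of a
#' raster scan runs along rows ("horizontal lines").
#'
#' @param heights numeric matrix of heights in nm; must be finite.
#' @param pixel_size pixel edge length in nm (isotropic, > 0).
#' @param name optional text label carried through reports.
#' @return An object of class `heightmap`: a list with elements `heights`,
#'   `pixel_size` and `name`.
#' @examples
#' hm <- heightmap(matrix(0, 8, 8), pixel_size = 2)
#' dim(hm$heights)
#' @export
heightmap <- function(heights, pixel_size, name = "") {
  if (!is.matrix(heights) || !is.numeric(heights))
    pg_stop("'heights' must be a numeric matrix", "pgafm_format_error")
  if (!all(is.finite(heights)))
    pg_stop("'heights' must be finite everywhere", "pgafm_format_error")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    pg_stop("'pixel_size' must be a single positive number (nm per pixel)",
            "pgafm_metadata_error")
  structure(list(heights = heights, pixel_size = as.numeric(pixel_size),
                 name = as.character(name)[1L]),
            class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %s%d x %d px, %.4g nm/px, height range [%.4g, %.4g] nm\n",
              if (nzchar(x$name)) paste0("'", x$name, "' ") else "",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

as_heightmap <- function(x) {
  if (inherits(x, "heightmap")) return(x)
  pg_stop("expected a 'heightmap' object", "pgafm_format_error")
}

#' Read a height map from disk
#'
#' Two plain formats are supported.
#'
#' * `ascii_grid`: a text file whose first line is `pixel_size_nm=<value>`
#'   followed by whitespace-separated rows of heights in nm. All rows must
#'   have the same number of values.
#' * `tiff`: a single-channel 32-bit float TIFF. Because float TIFF samples
#'   outside \[0, 1\] are not portable, heights are stored min-max normalised
#'   with the affine transform (`height_offset_nm`, `height_scale_nm`) and the
#'   pixel size recorded in a JSON sidecar `<path>.json`. A `pixel_size`
#'   argument overrides (or substitutes for) the sidecar pixel size; without a
#'   sidecar the stored values are taken as raw nm.
#'
#' The pixel size is never silently defaulted: if neither sidecar nor argument
#' provides it, reading fails with a metadata error.
#'
#' @param path file to read.
#' @param fmt `"ascii_grid"` or `"tiff"`; default guessed from the extension.
#' @param pixel_size optional pixel size override in nm.
#' @param name label for the returned map; defaults to the file name.
#' @return A [heightmap()].
#' @seealso [write_heightmap()]
#' @export
read_heightmap <- function(path, fmt = c("auto", "ascii_grid", "tiff"),
                           pixel_size = NULL, name = basename(path)) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    pg_stop(sprintf("file not found: %s", path), "pgafm_io_error")
  if (fmt == "auto")
    fmt <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  if (fmt == "ascii_grid") read_heightmap_ascii(path, pixel_size, name)
  else read_heightmap_tiff(path, pixel_size, name)
}

read_heightmap_ascii <- function(path, pixel_size, name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    pg_stop("ascii_grid needs a header line and at least one data row",
            "pgafm_format_error")
  hdr <- trimws(lines[1L])
  m <- regmatches(hdr, regexec("^pixel_size_nm=([-+0-9.eE]+)$", hdr))[[1L]]
  if (length(m) != 2L)
    pg_stop("ascii_grid header must be 'pixel_size_nm=<value>'",
            "pgafm_metadata_error")
  ps <- suppressWarnings(as.numeric(m[2L]))
  if (!is.null(pixel_size)) ps <- pixel_size
  if (!is.finite(ps) || ps <= 0)
    pg_stop("pixel size in header is missing or not positive",
            "pgafm_metadata_error")
  rows <- lapply(strsplit(trimws(lines[-1L]), "[[:space:]]+"), as.numeric)
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    pg_stop("ascii_grid rows have unequal lengths", "pgafm_format_error")
  if (anyNA(unlist(rows)))
    pg_stop("ascii_grid contains non-numeric values", "pgafm_format_error")
  heightmap(do.call(rbind, rows), ps, name)
}

tiff_sidecar_path <- function(path) paste0(path, ".json")

read_heightmap_tiff <- function(path, pixel_size, name) {
  raw <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] != 1L)
      pg_stop("TIFF must be single-channel", "pgafm_format_error")
    raw <- raw[, , 1L]
  }
  offset <- 0; scale <- 1; ps <- NULL
  sc <- tiff_sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    ps <- meta$pixel_size_nm
    if (!is.null(meta$height_offset_nm)) offset <- meta$height_offset_nm
    if (!is.null(meta$height_scale_nm)) scale <- meta$height_scale_nm
  }
  if (!is.null(pixel_size)) ps <- pixel_size
  if (is.null(ps))
    pg_stop(paste0("no pixel size: sidecar ", sc,
                   " is absent and no 'pixel_size' was given"),
            "pgafm_metadata_error")
  heightmap(raw * scale + offset, ps, name)
}

#' Write a height map to disk
#'
#' Writes either the self-describing text grid or a 32-bit float TIFF with a
#' JSON sidecar (see [read_heightmap()] for both dialects). Round-tripping
#' through either format reproduces the heights to better than 1e-6 nm for
#' nanometre-scale images.
#'
#' @param hm a [heightmap()].
#' @param path destination file.
#' @param fmt `"ascii_grid"` or `"tiff"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(hm, path, fmt = c("auto", "ascii_grid", "tiff")) {
  hm <- as_heightmap(hm)
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  if (fmt == "ascii_grid") {
    hdr <- sprintf("pixel_size_nm=%.17g", hm$pixel_size)
    body <- apply(hm$heights, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
    writeLines(c(hdr, body), path)
  } else {
    h <- hm$heights
    offset <- min(h)
    scale <- max(h) - offset
    norm <- if (scale > 0) (h - offset) / scale else h * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    jsonlite::write_json(
      list(pixel_size_nm = hm$pixel_size, height_offset_nm = offset,
           height_scale_nm = if (scale > 0) scale else 1, name = hm$name),
      tiff_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Tabular results (data frames, pore sets, order maps, profiles) are written
#' as CSV; everything else (orientation results, summaries, nested records) as
#' JSON with units embedded in the field names where applicable.
#'
#' @param results a result object from any analysis function, or a data frame.
#' @param path destination `.csv` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  tabular <- inherits(results, c("data.frame", "pore_set", "order_map",
                                 "line_profile"))
  if (tabular) {
    df <- as.data.frame(results)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass_deep(results), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}
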