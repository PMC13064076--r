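#' Two-channel fluorescence movie
#'
#' Container for a registered pair of green (GCaMP6s) and red (tdTomato)
#' pixel stacks with their spatial and temporal calibration. Stacks are
#' numeric 3D arrays with dimensions (y, x, frame).
#'
#' @param green,red Numeric 3D arrays of identical dimension, intensities in
#'   arbitrary units, non-negative.
#' @param pixel_size Pixel edge length in micrometers (> 0).
#' @param frame_interval Time between frames in seconds (> 0).
#'
#' @return A `two_channel_movie` object.
#' @export
two_channel_movie <- function(green, red, pixel_size, frame_interval) {
  stopifnot(
    is.array(green), is.array(red), length(dim(green)) == 3,
    identical(dim(green), dim(red)),
    pixel_size > 0, frame_interval > 0
  )
  if (min(green) < 0 || min(red) < 0) {
    stop("channel intensities must be non-negative (clip before construction)",
         call. = FALSE)
  }
  structure(
    list(green = green, red = red,
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "two_channel_movie"
  )
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "<two_channel_movie> %d x %d px, %d frames | %.3g um/px, %.3g s/frame (%.1f s total)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval, d[3] * x$frame_interval
  ))
  invisible(x)
}

#' Per-pixel dF/F_R movie
#'
#' The ratiometric activity signal (F - F_R)/F_R on the valid-pixel mask.
#' Pixels outside the mask hold `NA`.
#'
#' @param dff Numeric 3D array (y, x, frame) of dF/F_R values.
#' @param mask Logical matrix (y, x): TRUE where the reference is reliable.
#' @param pixel_size,frame_interval Spatial/temporal calibration.
#' @return A `dff_movie` object.
#' @export
dff_movie <- function(dff, mask, pixel_size, frame_interval) {
  stopifnot(
    is.array(dff), length(dim(dff)) == 3,
    is.matrix(mask), identical(dim(mask), dim(dff)[1:2]),
    pixel_size > 0, frame_interval > 0
  )
  structure(
    list(dff = dff, mask = mask,
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "dff_movie"
  )
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf(
    "<dff_movie> %d x %d px, %d frames | %d valid pixels | range [%.3g, %.3g]\n",
    d[1], d[2], d[3], sum(x$mask),
    suppressWarnings(min(x$dff, na.rm = TRUE)),
    suppressWarnings(max(x$dff, na.rm = TRUE))
  ))
  invisible(x)
}

#' Write a two-channel movie as multi-page TIFF files
#'
#' One 32-bit float multi-page TIFF per channel (`green.tif`, `red.tif`) plus
#' a `calibration.json` carrying pixel size and frame interval.
#'
#' @param movie A [two_channel_movie()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_movie_tiff <- function(movie, dir) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_movie_tiff() needs the 'tiff' and 'jsonlite' packages", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_pages <- function(a) lapply(seq_len(dim(a)[3]), function(t) a[, , t])
  tiff::writeTIFF(as_pages(movie$green), file.path(dir, "green.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(as_pages(movie$red), file.path(dir, "red.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size, frame_interval_s = movie$frame_interval),
    file.path(dir, "calibration.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a two-channel movie written by [write_movie_tiff()]
#'
#' @param dir Directory holding `green.tif`, `red.tif`, `calibration.json`.
#' @return A [two_channel_movie()].
#' @export
read_movie_tiff <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    stop("read_movie_tiff() needs the 'tiff' and 'jsonlite' packages", call. = FALSE)
  }
  stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  cal <- jsonlite::read_json(file.path(dir, "calibration.json"))
  two_channel_movie(
    green = stack(file.path(dir, "green.tif")),
    red = stack(file.path(dir, "red.tif")),
    pixel_size = cal$pixel_size_um,
    frame_interval = cal$frame_interval_s
  )
}
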