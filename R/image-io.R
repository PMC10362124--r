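#' Read a raster image as a grayscale double-precision matrix
#'
#' Reads PNG or TIFF (8- or 16-bit, 1 or 3 channels; an alpha channel is
#' dropped with a warning) and JPEG when the EBImage package is available.
#' Integer intensities are divided by the type maximum so the result lies in
#' \[0, 1\]; 3-channel inputs are collapsed with [to_gray()].
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return A [gray_image()].
#' @seealso [save_image()], [to_gray()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = try(png::readPNG(path), silent = TRUE),
    tif  = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("JPEG support requires the EBImage package", call. = FALSE)
      }
      try({
        e <- EBImage::readImage(path)
        a <- EBImage::imageData(e)
        # EBImage stores (x, y [, channel]); convert to (row, col [, channel])
        if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
      }, silent = TRUE)
    },
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
  )
  if (inherits(arr, "try-error")) {
    stop("failed to decode image file: ", path, call. = FALSE)
  }
  arr <- decode_channels(arr, path)
  gray_image(arr)
}

# Internal: collapse channel layouts to a single gray plane.
decode_channels <- function(arr, path = "<array>") {
  if (is.matrix(arr)) return(unclass(arr))
  if (length(dim(arr)) != 3L) {
    stop("unsupported image layout in ", path, call. = FALSE)
  }
  nc <- dim(arr)[3L]
  if (nc == 4L) {
    warning("dropping alpha channel of ", path, call. = FALSE)
    arr <- arr[, , 1:3, drop = FALSE]
    nc <- 3L
  }
  if (nc == 1L) return(arr[, , 1L])
  if (nc == 2L) { # gray + alpha
    warning("dropping alpha channel of ", path, call. = FALSE)
    return(arr[, , 1L])
  }
  if (nc != 3L) {
    stop("unsupported channel count (", nc, ") in ", path, call. = FALSE)
  }
  unclass(to_gray(arr))
}

#' Convert an RGB array to grayscale
#'
#' Uses the ITU-R BT.601 luma weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb a numeric array of dimension `h x w x 3` (channels last).
#' @return A [gray_image()].
#' @examples
#' rgb <- array(c(1, 0, 0), dim = c(3, 3, 3))
#' rgb[] <- rep(c(1, 0, 0), each = 9)
#' to_gray(rgb)[1, 1] # 0.299
#' @export
to_gray <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L) {
    stop("`rgb` must be an h x w x 3 array", call. = FALSE)
  }
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  gray_image(g)
}

#' Affinely rescale an image to \[0, 1\]
#'
#' Maps the minimum to 0 and the maximum to 1.  A constant image maps to all
#' zeros (the declared degenerate rule, so the result is always defined).
#' Filter outputs leave the nominal intensity range; this is the display/save
#' normalisation applied at the end of a pipeline, never silently before
#' metric computation.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return A [gray_image()] with values in \[0, 1\].
#' @export
rescale_for_display <- function(img) {
  m <- if (is.matrix(img)) unclass(img) else as.matrix(img)
  nbad <- sum(!is.finite(m))
  if (nbad > 0L) {
    stop("cannot rescale: ", nbad, " non-finite pixel(s)", call. = FALSE)
  }
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    m[] <- 0
  } else {
    m <- (m - lo) / (hi - lo)
  }
  wrap_image(m)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Values must already lie in \[0, 1\] (use [rescale_for_display()] first for
#' raw filter output).  PNG is written at 8-bit depth; TIFF supports 16-bit
#' integer and 32-bit float (`bits = 32`), the latter round-tripping exactly.
#'
#' @param img a [gray_image()] with values in \[0, 1\].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits TIFF bit depth: 8, 16 or 32 (float); ignored for PNG.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bits = 16L) {
  m <- check_image(img)
  if (min(m) < 0 || max(m) > 1) {
    stop("pixel values outside [0, 1]; apply rescale_for_display() first",
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, target = path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(m, where = path, bits.per.sample = as.integer(bits)),
    stop("unsupported output format '.", ext, "'; use PNG or TIFF",
         call. = FALSE)
  )
  invisible(path)
}
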