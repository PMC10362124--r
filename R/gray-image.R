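#' Grayscale image objects
#'
#' A `gray_image` is a plain numeric matrix of double-precision intensities
#' (nominal range \[0, 1\], rows = image rows) carrying the class attribute
#' `"gray_image"`.  Every filter in the package consumes and produces this
#' type.  All computation is done in double precision; values are allowed to
#' leave \[0, 1\] (filter outputs routinely do) and are only rescaled at
#' save/display time via [rescale_for_display()].
#'
#' @param pixels numeric matrix of intensities; at least 3 x 3, all finite.
#' @return A `gray_image` (numeric matrix with class `"gray_image"`).
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3 x 3 (got ", nrow(pixels), " x ",
         ncol(pixels), ")", call. = FALSE)
  }
  nbad <- sum(!is.finite(pixels))
  if (nbad > 0L) {
    stop("image contains ", nbad, " non-finite pixel(s)", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", class(matrix())))
}

#' @rdname gray_image
#' @param x object to coerce or test.
#' @export
as_gray_image <- function(x) {
  if (is_gray_image(x)) return(x)
  gray_image(as.matrix(x))
}

#' @rdname gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

# Internal: validate an image argument, returning a bare double matrix.
# Accepts gray_image or any numeric matrix so that pipelines stay friction-free.
check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`", arg, "` must be a numeric matrix or gray_image", call. = FALSE)
  }
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop("`", arg, "` must be at least 3 x 3", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("`", arg, "` contains non-finite pixels", call. = FALSE)
  }
  m <- unclass(img)
  storage.mode(m) <- "double"
  m
}

# Internal: re-wrap a matrix as gray_image without re-validating finiteness
# (used on outputs that are finite by construction).
wrap_image <- function(m) structure(m, class = c("gray_image", class(matrix())))

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range [%.4g, %.4g], mean %.4g\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}

#' Display a grayscale image
#'
#' Renders the image with `graphics::image()` in the usual raster orientation
#' (row 1 at the top), after an affine rescale to \[0, 1\].
#'
#' @param x a [gray_image()].
#' @param rescale rescale intensities to \[0, 1\] before display (default TRUE;
#'   filter outputs are typically unbounded).
#' @param ... passed to [graphics::image()].
#' @export
plot.gray_image <- function(x, rescale = TRUE, ...) {
  m <- check_image(x)
  if (rescale) m <- unclass(rescale_for_display(m))
  # transpose + reverse rows so the matrix displays in reading orientation
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(m) / ncol(m), zlim = range(m), ...)
  invisible(x)
}
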