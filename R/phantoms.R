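#' Phantom objects: images with analytic ground-truth edges
#'
#' A `phantom` pairs a [gray_image()] with the binary `edge_mask` of its
#' analytic shape boundaries, plus a `meta` list recording the generator name,
#' parameters and seed.  Phantoms stand in for photographic test material so
#' that edge quality can be scored against known truth instead of judged
#' visually.
#'
#' The shared rasterisation rule: working on the generator's integer label
#' grid (0 = background, k = shape k), a pixel is an edge pixel iff it
#' carries a shape label and at least one 4-neighbour carries a different
#' label.  Boundaries are therefore one pixel wide, on the shape side.
#'
#' @name phantom
NULL

new_phantom <- function(image, edge_mask, meta) {
  stopifnot(identical(dim(image), dim(edge_mask)))
  structure(list(image = wrap_image(image), edge_mask = edge_mask,
                 meta = meta),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> %d x %d, %d edge pixel(s)\n",
              x$meta$generator, nrow(x$image), ncol(x$image),
              sum(x$edge_mask)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, show_edges = TRUE, ...) {
  m <- unclass(rescale_for_display(x$image))
  if (show_edges) m[x$edge_mask] <- 1
  plot.gray_image(wrap_image(m), rescale = FALSE, ...)
}

#' Edge mask of a region-label grid
#'
#' Applies the package's rasterisation rule (see [phantom]): a pixel is an
#' edge pixel iff its label is non-background (`> 0`) and at least one of its
#' 4-neighbours carries a different label.
#'
#' @param labels integer matrix of region labels, 0 = background.
#' @return A logical matrix of the same shape.
#' @examples
#' lab <- matrix(0L, 128, 128); lab[55:74, 55:74] <- 1L
#' sum(edge_mask_from_labels(lab)) # 4*20 - 4 = 76
#' @export
edge_mask_from_labels <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  differs <- matrix(FALSE, h, w)
  differs[-h, ] <- differs[-h, ] | (labels[-h, ] != labels[-1, ])
  differs[-1, ] <- differs[-1, ] | (labels[-1, ] != labels[-h, ])
  differs[, -w] <- differs[, -w] | (labels[, -w] != labels[, -1])
  differs[, -1] <- differs[, -1] | (labels[, -1] != labels[, -w])
  differs & labels > 0L
}

#' Geometric shapes phantom
#'
#' Places 3–6 non-overlapping filled rectangles and disks with distinct gray
#' levels in \[0.2, 0.9\] on a 0.1 background, by seeded rejection sampling.
#' The edge mask marks the shape-side boundary pixels (see [phantom]).
#' Deterministic given the seed.
#'
#' @param h,w canvas size in pixels, `>= 64`.
#' @param seed integer RNG seed.
#' @return A [phantom].
#' @export
make_shapes_phantom <- function(h = 256L, w = 256L, seed = 1L) {
  if (h < 64 || w < 64) stop("canvas must be at least 64 x 64", call. = FALSE)
  gen <- withr::with_seed(as.integer(seed), {
    n_shapes <- sample(3:6, 1L)
    levels <- sample(seq(0.2, 0.9, length.out = 12L), n_shapes)
    labels <- matrix(0L, h, w)
    occupied <- matrix(FALSE, h, w)  # shapes plus a 2-px clearance
    placed <- 0L
    tries <- 0L
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    while (placed < n_shapes && tries < 500L) {
      tries <- tries + 1L
      is_disk <- stats::runif(1) < 0.5
      if (is_disk) {
        r <- sample(seq(6L, max(7L, min(h, w) %/% 8L)), 1L)
        cy <- sample(seq(r + 3L, h - r - 2L), 1L)
        cx <- sample(seq(r + 3L, w - r - 2L), 1L)
        shape <- (rows - cy)^2 + (cols - cx)^2 <= r^2
        clear <- (rows - cy)^2 + (cols - cx)^2 <= (r + 2L)^2
      } else {
        sh <- sample(seq(8L, max(9L, h %/% 5L)), 1L)
        sw <- sample(seq(8L, max(9L, w %/% 5L)), 1L)
        y0 <- sample(seq(3L, h - sh - 2L), 1L)
        x0 <- sample(seq(3L, w - sw - 2L), 1L)
        shape <- rows >= y0 & rows < y0 + sh & cols >= x0 & cols < x0 + sw
        clear <- rows >= y0 - 2L & rows < y0 + sh + 2L &
                 cols >= x0 - 2L & cols < x0 + sw + 2L
      }
      if (any(occupied & clear)) next
      placed <- placed + 1L
      labels[shape] <- placed
      occupied <- occupied | clear
    }
    if (placed < 3L) {
      stop("could not place at least 3 shapes on a ", h, " x ", w, " canvas",
           call. = FALSE)
    }
    img <- matrix(0.1, h, w)
    for (k in seq_len(placed)) img[labels == k] <- levels[k]
    list(img = img, labels = labels, n = placed)
  })
  new_phantom(gen$img, edge_mask_from_labels(gen$labels),
              list(generator = "shapes", h = h, w = w, seed = seed,
                   n_shapes = gen$n))
}

#' Vertical step-edge phantom
#'
#' Columns with 0-based index `< column` take the value `low`, the rest
#' `high`.  The edge mask marks the two columns adjacent to the
#' discontinuity (the last low and first high column), even when
#' `low == high`.
#'
#' @param h,w canvas size, `>= 3`.
#' @param column 0-based index of the first high column, `0 < column < w`.
#' @param low,high intensity levels in \[0, 1\].
#' @return A [phantom].
#' @export
make_step_edge <- function(h = 128L, w = 128L, column = w %/% 2L,
                           low = 0, high = 1) {
  if (column <= 0 || column >= w) {
    stop("`column` must satisfy 0 < column < w", call. = FALSE)
  }
  img <- matrix(low, h, w)
  img[, (column + 1L):w] <- high
  mask <- matrix(FALSE, h, w)
  mask[, c(column, column + 1L)] <- TRUE
  new_phantom(img, mask,
              list(generator = "step", h = h, w = w, column = column,
                   low = low, high = high))
}

#' Near-infrared tube-in-tissue phantom
#'
#' Emulates a fluorescence image of a dye-filled tube buried under scattering
#' tissue: a rotated bright rectangle (the tube) over a dim background, with
#' mild seeded multiplicative texture, blurred by a normalised Gaussian to
#' mimic tissue scattering.  The edge mask is the tube boundary before
#' blurring.  This is a synthetic analog of such an acquisition, not a
#' reproduction of any particular instrument's output.
#'
#' @param h,w canvas size, `>= 64`.
#' @param tube_width tube width in pixels, `>= 3`.
#' @param angle tube orientation in degrees.
#' @param blur_sigma Gaussian blur scale in pixels (0 disables blurring).
#' @param background,peak intensity levels, `0 <= background < peak <= 1`.
#' @param texture_amp relative amplitude of the multiplicative texture
#'   (0 disables it).
#' @param seed integer RNG seed for the texture.
#' @return A [phantom].
#' @export
make_nir_tube_phantom <- function(h = 256L, w = 256L, tube_width = 20L,
                                  angle = 30, blur_sigma = 3,
                                  background = 0.1, peak = 0.8,
                                  texture_amp = 0.05, seed = 1L) {
  if (h < 64 || w < 64) stop("canvas must be at least 64 x 64", call. = FALSE)
  if (tube_width < 3) stop("`tube_width` must be >= 3", call. = FALSE)
  if (background < 0 || peak > 1 || background >= peak) {
    stop("need 0 <= background < peak <= 1", call. = FALSE)
  }
  theta <- angle * pi / 180
  len <- 0.6 * min(h, w)
  # tube interior in rotated coordinates about the canvas centre
  rows <- matrix(seq_len(h) - (h + 1) / 2, h, w)
  cols <- matrix(seq_len(w) - (w + 1) / 2, h, w, byrow = TRUE)
  u <- cols * cos(theta) + rows * sin(theta)   # along the tube
  v <- -cols * sin(theta) + rows * cos(theta)  # across the tube
  tube <- abs(u) <= len / 2 & abs(v) <= tube_width / 2
  # the tube must fit: no interior pixel on the canvas border
  border <- matrix(FALSE, h, w)
  border[c(1L, h), ] <- TRUE; border[, c(1L, w)] <- TRUE
  if (any(tube & border)) {
    stop("tube does not fit the canvas at this angle/width", call. = FALSE)
  }
  if (!any(tube)) stop("degenerate tube (empty interior)", call. = FALSE)
  img <- matrix(background, h, w)
  img[tube] <- peak
  mask <- edge_mask_from_labels(matrix(as.integer(tube), h, w))
  if (texture_amp > 0) {
    tex <- withr::with_seed(as.integer(seed),
                            matrix(stats::runif(h * w, -1, 1), h, w))
    tex <- gaussian_blur(tex, 4)
    tex <- tex / max(abs(tex))
    img <- img * (1 + texture_amp * tex)
  }
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  new_phantom(img, mask,
              list(generator = "nir_tube", h = h, w = w,
                   tube_width = tube_width, angle = angle,
                   blur_sigma = blur_sigma, background = background,
                   peak = peak, texture_amp = texture_amp, seed = seed))
}
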