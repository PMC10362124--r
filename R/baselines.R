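#' Edge-map result objects
#'
#' An `edge_map` bundles a nonnegative response `magnitude`, the scalar
#' `threshold` used to binarise it, and the binary `mask = magnitude >
#' threshold` (strict, so a flat zero response yields an empty mask even at
#' threshold 0).  The `"auto"` threshold rule used throughout the package is
#' `mean(magnitude) + sd(magnitude)`: scale-free and deterministic.
#'
#' @param magnitude nonnegative numeric matrix of responses.
#' @param threshold scalar threshold, or `"auto"` for mean + 1 sd.
#' @return An object of class `"edge_map"` with fields `magnitude`, `mask`,
#'   `threshold`.
#' @export
edge_map <- function(magnitude, threshold = "auto") {
  if (any(magnitude < 0)) stop("`magnitude` must be >= 0", call. = FALSE)
  thr <- resolve_threshold(magnitude, threshold)
  structure(list(magnitude = magnitude, mask = magnitude > thr,
                 threshold = thr),
            class = "edge_map")
}

#' @rdname edge_map
#' @export
auto_threshold <- function(magnitude) {
  mean(magnitude) + stats::sd(as.vector(magnitude))
}

resolve_threshold <- function(magnitude, threshold) {
  if (identical(threshold, "auto")) return(auto_threshold(magnitude))
  if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop("`threshold` must be a scalar or \"auto\"", call. = FALSE)
  }
  threshold
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, threshold %.4g, %d edge pixel(s) (%.2f%%)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$threshold,
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
plot.edge_map <- function(x, ...) {
  plot.gray_image(wrap_image(x$mask * 1), rescale = FALSE, ...)
}

#' Classical gradient edge operators
#'
#' Convolves with the standard Sobel/Prewitt 3x3 or Roberts 2x2 kernel pairs
#' (reflective borders), takes `magnitude = sqrt(Gx^2 + Gy^2)`, and
#' binarises.  These are the conventional operators the special-function
#' filters are compared against under heavy impulse noise.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param operator `"sobel"`, `"prewitt"` or `"roberts"`.
#' @param threshold scalar or `"auto"` (mean + 1 sd of the magnitude).
#' @return An [edge_map()].
#' @examples
#' step <- make_step_edge(16, 16, column = 8)
#' max(gradient_edge(step$image, "sobel")$magnitude) # 4 at the edge
#' @export
gradient_edge <- function(img, operator = c("sobel", "prewitt", "roberts"),
                          threshold = "auto") {
  m <- check_image(img)
  operator <- match.arg(operator)
  ks <- switch(operator,
    sobel = list(gx = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
                 gy = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)),
    prewitt = list(gx = matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3),
                   gy = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)),
    roberts = list(gx = matrix(c(1, 0, 0, -1), 2, 2),
                   gy = matrix(c(0, -1, 1, 0), 2, 2))
  )
  gx <- conv2_reflect(m, ks$gx)
  gy <- conv2_reflect(m, ks$gy)
  edge_map(sqrt(gx^2 + gy^2), threshold)
}

#' Laplacian-of-Gaussian edge operator
#'
#' Gaussian smoothing at `sigma` followed by a 3x3 Laplacian; the magnitude
#' is `|response|` at pixels where the response changes sign against a
#' 4-neighbour (zero-crossings), 0 elsewhere.  Impulse noise injects
#' high-frequency energy, so on a salt-and-pepper image the mask is denser
#' than on the clean image at the same threshold — the operator does not
#' remove that noise.
#'
#' @inheritParams gradient_edge
#' @param sigma Gaussian smoothing scale in pixels, `> 0`.
#' @return An [edge_map()].
#' @export
log_edge <- function(img, sigma = 1, threshold = "auto") {
  m <- check_image(img)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- conv2_reflect(gaussian_blur(m, sigma), lap)
  h <- nrow(resp); w <- ncol(resp)
  s <- sign(resp)
  zc <- matrix(FALSE, h, w)
  zc[-h, ] <- zc[-h, ] | (s[-h, ] * s[-1, ] < 0)
  zc[-1, ] <- zc[-1, ] | (s[-1, ] * s[-h, ] < 0)
  zc[, -w] <- zc[, -w] | (s[, -w] * s[, -1] < 0)
  zc[, -1] <- zc[, -1] | (s[, -1] * s[, -w] < 0)
  edge_map(abs(resp) * zc, threshold)
}

# Rotated coordinate grids for oriented kernels.
rot_coords <- function(radius, theta) {
  x <- outer(rep(1, 2 * radius + 1), (-radius):radius)  # column offsets
  y <- outer((-radius):radius, rep(1, 2 * radius + 1))  # row offsets
  list(u = x * cos(theta) + y * sin(theta),
       v = -x * sin(theta) + y * cos(theta))
}

#' Gabor filter bank
#'
#' Convolves with zero-DC complex Gabor kernels (isotropic Gaussian envelope
#' times a complex sinusoid) at every frequency/orientation combination and
#' takes the pixelwise maximum of the response moduli.  The envelope scale is
#' tied to the frequency (`sigma = 0.56 / frequency`, about one octave of
#' bandwidth).
#'
#' @inheritParams gradient_edge
#' @param frequencies spatial frequencies in cycles/pixel, each in (0, 0.5).
#' @param n_orientations number of orientations spread over \[0, pi).
#' @return An [edge_map()].
#' @export
gabor_bank <- function(img, frequencies = c(0.1, 0.2), n_orientations = 4L,
                       threshold = "auto") {
  m <- check_image(img)
  if (length(frequencies) < 1L) {
    stop("at least one frequency is required", call. = FALSE)
  }
  if (any(frequencies <= 0 | frequencies >= 0.5)) {
    stop("frequencies must lie in (0, 0.5) cycles/pixel (Nyquist)",
         call. = FALSE)
  }
  if (n_orientations < 1L) {
    stop("at least one orientation is required", call. = FALSE)
  }
  thetas <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  mag <- matrix(0, nrow(m), ncol(m))
  for (f in frequencies) {
    sigma <- 0.56 / f
    radius <- ceiling(2.5 * sigma)
    for (theta in thetas) {
      rc <- rot_coords(radius, theta)
      env <- exp(-(rc$u^2 + rc$v^2) / (2 * sigma^2))
      re <- env * cos(2 * pi * f * rc$u)
      im <- env * sin(2 * pi * f * rc$u)
      re <- re - env * sum(re) / sum(env)  # zero DC
      im <- im - env * sum(im) / sum(env)
      resp <- sqrt(conv2_reflect(m, re)^2 + conv2_reflect(m, im)^2)
      mag <- pmax(mag, resp)
    }
  }
  edge_map(mag, threshold)
}

# Build the oriented matched-filter kernel bank once (used by matched_filter
# and exercised directly in tests).
matched_kernels <- function(sigma, len, n_orientations) {
  radius <- ceiling(max(3 * sigma, len / 2))
  thetas <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  lapply(thetas, function(theta) {
    rc <- rot_coords(radius, theta)
    support <- abs(rc$u) <= 3 * sigma & abs(rc$v) <= len / 2
    k <- matrix(0, nrow(rc$u), ncol(rc$u))
    k[support] <- -exp(-rc$u[support]^2 / (2 * sigma^2))
    vals <- k[support]
    if (isTRUE(stats::sd(vals) == 0)) {
      stop("degenerate matched-filter kernel (constant support)",
           call. = FALSE)
    }
    k[support] <- vals - mean(vals)  # zero-DC over the support
    k
  })
}

#' Oriented matched filter for curvilinear structures
#'
#' Line-detection kernels with a Gaussian cross-profile `-exp(-x^2/(2
#' sigma^2))`, constant along the line over `length` pixels, mean-subtracted
#' over their support so each kernel sums to zero, rotated over
#' `n_orientations` angles.  The magnitude is the pixelwise maximum of the
#' absolute responses, so bright-on-dark and dark-on-bright lines are both
#' detected.  Defaults follow the classical vessel-detection configuration
#' (sigma 2, length 9, 12 orientations).
#'
#' @inheritParams gradient_edge
#' @param sigma cross-profile scale in pixels, `> 0`.
#' @param length kernel extent along the line, `>= 1` pixels.
#' @param n_orientations number of orientations over \[0, pi), `>= 1`.
#' @return An [edge_map()].
#' @export
matched_filter <- function(img, sigma = 2, length = 9, n_orientations = 12L,
                           threshold = "auto") {
  m <- check_image(img)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  if (n_orientations < 1L) {
    stop("at least one orientation is required", call. = FALSE)
  }
  kernels <- matched_kernels(sigma, length, n_orientations)
  mag <- matrix(0, nrow(m), ncol(m))
  for (k in kernels) mag <- pmax(mag, abs(conv2_reflect(m, k)))
  edge_map(mag, threshold)
}
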