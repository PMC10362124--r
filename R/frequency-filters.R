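#' Parameters of the cosh-acosh frequency filter
#'
#' The transfer function is a Chebyshev-type response built from the identity
#' `cosh(N * acosh(u)) = cos(N * acos(u)) = T_N(u)`.  With the frequency-plane
#' distance `D` and reference distance `D0`, the gain at each frequency is
#' `H = 1 / (1 + eps^2 * CNx^n4)` with `CNx = |T_order(D0 / D)|^n5`.  Low
#' frequencies (`D < D0`, the cosh branch) are monotonically suppressed down
#' to ~0 at DC, so the filter acts as a high-pass edge extractor; beyond `D0`
#' the cosine branch produces bounded passband ripple between `1/(1 + eps^2)`
#' and 1.
#'
#' @param order Chebyshev order `N > 0` (independent of the grid half-width;
#'   using the half-width itself would collapse the gain to 0 everywhere).
#' @param n5 power applied to `|T_N(u)|` before the denominator.
#' @param n4 power on `CNx` inside the denominator.
#' @param eps ripple constant, `>= 0`; `eps = 0` gives the all-pass identity.
#' @return An object of class `c("cosh_acosh_params", "filter_params")`.
#' @export
cosh_acosh_params <- function(order = 4, n5 = 1, n4 = 2, eps = 1) {
  stopifnot(length(order) == 1L, length(n5) == 1L, length(n4) == 1L,
            length(eps) == 1L)
  if (order <= 0) stop("`order` must be > 0", call. = FALSE)
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  structure(list(order = order, n5 = n5, n4 = n4, eps = eps),
            class = c("cosh_acosh_params", "filter_params"))
}

#' Parameters of the sech-asech frequency filter
#'
#' Uses the reciprocal continuation `sech(lam * asech(u)) =
#' 1 / cosh(lam * acosh(1/u))`: the gain is `H = 1 / (1 + eps^2 * CNx2^2)`
#' with `CNx2 = |1 / T_lam(1/u)|^nn` and `u = D0 / D`.  High frequencies pass
#' (`H -> 1` as `D -> Inf`); inside `D < D0` the cosine branch makes `CNx2`
#' oscillate, producing the characteristic rippled ("corrugated") rendering.
#'
#' @param lam order `lambda > 0`.
#' @param nn outer power on the sech term; larger values darken the output.
#' @param eps ripple constant, `>= 0`; `eps = 0` gives the all-pass identity.
#' @return An object of class `c("sech_asech_params", "filter_params")`.
#' @export
sech_asech_params <- function(lam = 4, nn = 24, eps = 1) {
  stopifnot(length(lam) == 1L, length(nn) == 1L, length(eps) == 1L)
  if (lam <= 0) stop("`lam` must be > 0", call. = FALSE)
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  structure(list(lam = lam, nn = nn, eps = eps),
            class = c("sech_asech_params", "filter_params"))
}

#' Frequency-plane distance map
#'
#' Builds the per-frequency radial coordinate
#' `D(i, j) = |i - m1|^n3 + |j - n1|^n3` around the centre of the shifted
#' spectrum, with `m1 = floor(h/2)` and `n1 = floor(w/2)` in 0-based indices.
#' Absolute values keep `D` a nonnegative distance for any `n3`.  The
#' reference distance `D0` defaults to `0.05 * m1`, i.e. 5% of the half-height
#' in the same units as `D` — a small low-frequency core.
#'
#' @param h,w image size in pixels, `>= 3`.
#' @param n3 distance exponent, `> 0` (default 2, Euclidean-squared).
#' @param d0 reference distance `> 0`; default `0.05 * floor(h/2)`.
#' @return An object of class `"freq_grid"`: list with `D` (h x w matrix),
#'   `m1`, `n1_half`, `n3`, `d0`.
#' @examples
#' g <- distance_map(8, 8)
#' g$D[5, 5] # centre (0-based index 4,4) -> 0
#' @export
distance_map <- function(h, w, n3 = 2, d0 = NULL) {
  stopifnot(length(h) == 1L, length(w) == 1L)
  if (h < 3 || w < 3) stop("`h` and `w` must be >= 3", call. = FALSE)
  if (n3 <= 0) stop("`n3` must be > 0", call. = FALSE)
  m1 <- h %/% 2L
  n1 <- w %/% 2L
  if (is.null(d0)) d0 <- 0.05 * m1
  if (d0 <= 0) stop("`d0` must be > 0", call. = FALSE)
  di <- abs(seq_len(h) - 1L - m1)^n3
  dj <- abs(seq_len(w) - 1L - n1)^n3
  D <- outer(di, dj, "+")
  structure(list(D = D, m1 = m1, n1_half = n1, n3 = n3, d0 = d0),
            class = "freq_grid")
}

#' Real Chebyshev evaluation via hyperbolic/trigonometric continuation
#'
#' Evaluates `cosh(N * acosh(u))` for `u >= 1` and its analytic continuation
#' `cos(N * acos(u))` for `0 <= u < 1`.  At integer `N` both branches coincide
#' with the Chebyshev polynomial `T_N(u)`; the continuation keeps the value
#' real across the whole nonnegative axis, which is what lets the transfer
#' functions be evaluated at every frequency.
#'
#' @param order order `N > 0` (need not be an integer).
#' @param u nonnegative numeric vector/matrix of arguments.
#' @return Values of the continued Chebyshev function, same shape as `u`.
#' @examples
#' chebyshev_cosh(3, 2) # T_3(2) = 4*8 - 6 = 26
#' @export
chebyshev_cosh <- function(order, u) {
  if (order <= 0) stop("`order` must be > 0", call. = FALSE)
  if (any(u < 0, na.rm = TRUE)) {
    stop("`u` must be nonnegative", call. = FALSE)
  }
  out <- u
  hi <- u >= 1
  out[hi] <- cosh(order * acosh(u[hi]))
  out[!hi] <- cos(order * acos(u[!hi]))
  out
}

# Internal: wrap a centred gain matrix as a transfer_function.
transfer_function <- function(H) {
  structure(H, class = c("transfer_function", class(matrix())),
            centering = "centered")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d x %d (centered), gain range [%.3g, %.3g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.transfer_function <- function(x, ...) {
  plot.gray_image(wrap_image(unclass(x)), rescale = FALSE, ...)
}

# Internal: 1/(1 + eps^2 * t), capped so the gain stays strictly positive
# and finite even when t overflows.
cheb_gain <- function(t, eps) {
  denom <- 1 + eps^2 * t
  denom[!is.finite(denom) | denom > .Machine$double.xmax] <- .Machine$double.xmax
  1 / denom
}

#' Cosh-acosh transfer function
#'
#' Computes the centred gain grid `H = 1 / (1 + eps^2 * CNx^n4)` with
#' `CNx = |chebyshev_cosh(order, D0/D)|^n5` (see [cosh_acosh_params()]).
#' The centre pixel (`D = 0`) is guarded by flooring `D` at `d0 * 1e-12`, so
#' the DC gain is a well-defined positive value ~0.  `H` is real, lies in
#' (0, 1], and is symmetric under 180-degree rotation about the grid centre,
#' which guarantees a real filtered image.
#'
#' @param h,w image size in pixels.
#' @param params a [cosh_acosh_params()] record.
#' @param grid optional [distance_map()]; built with defaults when omitted.
#' @return A `transfer_function` (h x w gain matrix, centred indexing).
#' @export
cosh_acosh_transfer <- function(h, w, params = cosh_acosh_params(),
                                grid = NULL) {
  if (!inherits(params, "cosh_acosh_params")) {
    stop("`params` must be created by cosh_acosh_params()", call. = FALSE)
  }
  if (is.null(grid)) grid <- distance_map(h, w)
  if (!identical(dim(grid$D), c(as.integer(h), as.integer(w)))) {
    stop("`grid` shape does not match (h, w)", call. = FALSE)
  }
  D <- pmax(grid$D, grid$d0 * 1e-12)
  u <- grid$d0 / D
  cnx <- abs(chebyshev_cosh(params$order, u))^params$n5
  transfer_function(cheb_gain(cnx^params$n4, params$eps))
}

#' Sech-asech transfer function
#'
#' Computes `H = 1 / (1 + eps^2 * CNx2^2)` with
#' `CNx2 = |1 / chebyshev_cosh(lam, 1/u)|^nn`, `u = D0/D`, using the
#' reciprocal continuation `sech(lam * asech(u)) = 1/cosh(lam * acosh(1/u))`
#' (see [sech_asech_params()]).  Zeros of the cosine branch make `CNx2`
#' overflow; those gains saturate to ~0 (largest-finite-double cap) rather
#' than failing.  `H` is real, in (0, 1], and rotation-symmetric.
#'
#' @inheritParams cosh_acosh_transfer
#' @param params a [sech_asech_params()] record.
#' @return A `transfer_function` (h x w gain matrix, centred indexing).
#' @export
sech_asech_transfer <- function(h, w, params = sech_asech_params(),
                                grid = NULL) {
  if (!inherits(params, "sech_asech_params")) {
    stop("`params` must be created by sech_asech_params()", call. = FALSE)
  }
  if (is.null(grid)) grid <- distance_map(h, w)
  if (!identical(dim(grid$D), c(as.integer(h), as.integer(w)))) {
    stop("`grid` shape does not match (h, w)", call. = FALSE)
  }
  D <- pmax(grid$D, grid$d0 * 1e-12)
  u <- grid$d0 / D
  tc <- chebyshev_cosh(params$lam, 1 / u)
  cnx2 <- abs(1 / tc)^params$nn
  over <- !is.finite(cnx2)
  if (any(over)) cnx2[over] <- .Machine$double.xmax
  transfer_function(cheb_gain(cnx2^2, params$eps))
}

# Index permutation that moves the centred origin (0-based floor(n/2)) to
# element 1: the inverse FFT shift.
ifftshift_index <- function(n) ((seq_len(n) - 1L + n %/% 2L) %% n) + 1L

#' Apply a centred transfer function in the Fourier domain
#'
#' Forward 2D FFT of the image, pointwise multiplication with the gain grid
#' (whose indexing is centred, so it is inverse-shifted to match the raw
#' spectrum layout), inverse FFT, and return of the real part.  A
#' rotation-symmetric real `H` guarantees the imaginary residue is round-off
#' only; the function asserts it is below `1e-9` of the real magnitude.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param H a `transfer_function` (or plain matrix) matching the image shape.
#' @return A [gray_image()] with the filtered (unclipped) intensities.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' allpass <- transfer_function_identity(8, 8)
#' max(abs(apply_frequency_filter(img, allpass) - img)) < 1e-10
#' @export
apply_frequency_filter <- function(img, H) {
  m <- check_image(img)
  Hm <- unclass(H)
  if (!identical(dim(Hm), dim(m))) {
    stop("transfer function shape ", paste(dim(Hm), collapse = "x"),
         " does not match image shape ", paste(dim(m), collapse = "x"),
         call. = FALSE)
  }
  G <- stats::fft(m)
  Hu <- Hm[ifftshift_index(nrow(m)), ifftshift_index(ncol(m))]
  S <- G * Hu
  out <- stats::fft(S, inverse = TRUE) / length(S)
  resid <- max(abs(Im(out)))
  scale <- max(max(abs(Re(out))), 1)
  if (resid > 1e-9 * scale) {
    stop("internal error: imaginary residue ", format(resid),
         " exceeds tolerance; transfer function is not rotation-symmetric",
         call. = FALSE)
  }
  wrap_image(Re(out))
}

#' All-pass transfer function (identity)
#'
#' @param h,w grid size.
#' @return A `transfer_function` of all ones.
#' @export
transfer_function_identity <- function(h, w) {
  transfer_function(matrix(1, h, w))
}

#' Cosh-acosh frequency filter (end to end)
#'
#' Convenience wrapper: builds the [distance_map()], the
#' [cosh_acosh_transfer()], and applies it with [apply_frequency_filter()].
#'
#' @inheritParams exp_filter
#' @param params a [cosh_acosh_params()] record.
#' @param n3 distance exponent for the frequency grid.
#' @param d0 reference distance; default `0.05 * floor(h/2)`.
#' @return A [gray_image()].
#' @export
cosh_acosh_filter <- function(img, params = cosh_acosh_params(), n3 = 2,
                              d0 = NULL) {
  m <- check_image(img)
  grid <- distance_map(nrow(m), ncol(m), n3 = n3, d0 = d0)
  H <- cosh_acosh_transfer(nrow(m), ncol(m), params, grid)
  apply_frequency_filter(m, H)
}

#' Sech-asech frequency filter (end to end)
#'
#' @inheritParams cosh_acosh_filter
#' @param params a [sech_asech_params()] record.
#' @return A [gray_image()].
#' @export
sech_asech_filter <- function(img, params = sech_asech_params(), n3 = 2,
                              d0 = NULL) {
  m <- check_image(img)
  grid <- distance_map(nrow(m), ncol(m), n3 = n3, d0 = d0)
  H <- sech_asech_transfer(nrow(m), ncol(m), params, grid)
  apply_frequency_filter(m, H)
}

#' Radial profile of a transfer function along a 1D distance grid
#'
#' Evaluates the scalar gain formula of either frequency filter on an
#' arbitrary grid of distance values `D` — the ripple diagnostic used to
#' count oscillations of the gain inside/outside the reference distance
#' without the coarse sampling of an actual pixel grid.
#'
#' @param params a [cosh_acosh_params()] or [sech_asech_params()] record.
#' @param D numeric vector of distance values, `>= 0`.
#' @param d0 reference distance, `> 0`.
#' @return A data.frame with columns `D` and `H`.
#' @export
transfer_radial_profile <- function(params, D, d0) {
  stopifnot(d0 > 0, all(D >= 0))
  Dg <- pmax(D, d0 * 1e-12)
  u <- d0 / Dg
  H <- if (inherits(params, "cosh_acosh_params")) {
    cnx <- abs(chebyshev_cosh(params$order, u))^params$n5
    cheb_gain(cnx^params$n4, params$eps)
  } else if (inherits(params, "sech_asech_params")) {
    tc <- chebyshev_cosh(params$lam, 1 / u)
    cnx2 <- abs(1 / tc)^params$nn
    cnx2[!is.finite(cnx2)] <- .Machine$double.xmax
    cheb_gain(cnx2^2, params$eps)
  } else {
    stop("`params` must be a frequency-filter parameter record", call. = FALSE)
  }
  data.frame(D = D, H = H)
}

#' Export a transfer function for inspection
#'
#' Writes the gain grid as a 32-bit float TIFF (values already in (0, 1]).
#'
#' @param H a `transfer_function`.
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
save_transfer_function <- function(H, path) {
  tiff::writeTIFF(unclass(H), where = path, bits.per.sample = 32L)
  invisible(path)
}
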