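#' Parameters of the exponential ("exp") intensity filter
#'
#' The exp filter maps each pixel `tt` to `a * exp(-q * (tt - b)^n2 / c^2)`.
#' With even `n2` and `q > 0` this is a Gaussian-kernel-like band selector
#' centred on intensity `b`: pixels near `b` map to the maximum `a`, pixels far
#' from `b` are suppressed, which is what turns region interiors of distinct
#' gray levels into separable bands (the mechanism behind its edge
#' extraction).  With odd `n2` the exponent changes sign across `b`, so pixels
#' darker than `b` are amplified above `a` and the output is globally brighter
#' than for the adjacent even order.
#'
#' @param a output scale (dimensionless); the filter's maximum for even `n2`.
#' @param q decay rate, `> 0`; larger `q` narrows the selected intensity band.
#' @param b intensity offset (same units as pixels); the band centre.
#' @param n2 positive integer progression exponent; parity flips the
#'   bright/dark character of the output.
#' @param c width constant, non-zero; enters as `c^2`.
#' @return An object of class `c("exp_params", "filter_params")`.
#' @export
exp_params <- function(a = 1, q = 2, b = 0.5, n2 = 8L, c = 1) {
  stopifnot(is.numeric(a), is.numeric(q), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(q) == 1L, length(b) == 1L,
            length(n2) == 1L, length(c) == 1L)
  if (!is.numeric(n2) || n2 < 1 || n2 != round(n2)) {
    stop("`n2` must be a positive integer (parity is meaningful only then)",
         call. = FALSE)
  }
  if (q <= 0) stop("`q` must be > 0", call. = FALSE)
  if (c == 0) stop("`c` must be non-zero", call. = FALSE)
  structure(list(a = a, q = q, b = b, n2 = as.integer(n2), c = c),
            class = c("exp_params", "filter_params"))
}

#' Parameters of the sinh-asinh-r intensity filter
#'
#' The filter first rescales intensities, `r = tt / eta`, then composes
#' hyperbolic sine with its inverse, `z = sinh(a1 * asinh(r + a2) * r^a3)`,
#' and finally applies an outer power `u4 = z^a4`.  Powers of negative bases
#' are taken sign-preservingly (`sign(x) |x|^p`) so fractional exponents never
#' produce complex values.
#'
#' @param eta intensity divisor, non-zero.
#' @param a1 inner scale.
#' @param a2 inner offset.
#' @param a3 power on `r`, `> 0`; the one constant with a visible effect on
#'   the extracted edges.
#' @param a4 outer power, `> 0`.
#' @return An object of class `c("sinh_asinh_params", "filter_params")`.
#' @export
sinh_asinh_params <- function(eta = 1, a1 = 1, a2 = 0.1, a3 = 2, a4 = 1) {
  stopifnot(length(eta) == 1L, length(a1) == 1L, length(a2) == 1L,
            length(a3) == 1L, length(a4) == 1L)
  if (eta == 0) stop("`eta` must be non-zero", call. = FALSE)
  if (a3 <= 0) stop("`a3` must be > 0", call. = FALSE)
  if (a4 <= 0) stop("`a4` must be > 0", call. = FALSE)
  structure(list(eta = eta, a1 = a1, a2 = a2, a3 = a3, a4 = a4),
            class = c("sinh_asinh_params", "filter_params"))
}

# sign-preserving power: real for any base and exponent
spow <- function(x, p) sign(x) * abs(x)^p

# Replace non-finite values by the largest finite double (sign kept) and warn.
# Odd exponents can drive exp()/sinh() past the double range for extreme
# inputs; the policy is saturate-and-continue, never NaN/Inf.
saturate <- function(x, what) {
  bad <- !is.finite(x)
  if (any(bad)) {
    x[bad & is.nan(x)] <- 0
    x[bad] <- sign(x[bad]) * .Machine$double.xmax
    warning(sum(bad), " pixel(s) saturated to the largest finite double in ",
            what, call. = FALSE)
  }
  x
}

# Apply a pointwise transform either to the whole image or, when
# paper_loop = TRUE, only to the 1-based interior rows/cols 3..(n-1),
# the literal loop range of the published procedure.
apply_pointwise <- function(img, fn, paper_loop) {
  if (!paper_loop) return(fn(img))
  out <- img
  h <- nrow(img); w <- ncol(img)
  rows <- 3:(h - 1L); cols <- 3:(w - 1L)
  out[rows, cols] <- fn(img[rows, cols, drop = FALSE])
  out
}

#' Exponential ("exp") intensity filter
#'
#' Pointwise transform `u = a * exp(-q * (tt - b)^n2 / c^2)` (see
#' [exp_params()]).  Output is not clipped to \[0, 1\]; use
#' [rescale_for_display()] before saving.  The transform is applied to every
#' pixel by default; `paper_loop = TRUE` restricts it to the interior range
#' `3..(h-1) x 3..(w-1)` (1-based) of the original iterative formulation,
#' leaving a border untouched.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param params an [exp_params()] record.
#' @param paper_loop apply only to the literal interior loop range.
#' @return A [gray_image()] of filtered intensities.
#' @examples
#' ph <- make_shapes_phantom(64, 64, seed = 1)
#' dark  <- exp_filter(ph$image, exp_params(n2 = 8))
#' bright <- exp_filter(ph$image, exp_params(n2 = 9))
#' mean_brightness(bright) > mean_brightness(dark)
#' @export
exp_filter <- function(img, params = exp_params(), paper_loop = FALSE) {
  m <- check_image(img)
  if (!inherits(params, "exp_params")) {
    stop("`params` must be created by exp_params()", call. = FALSE)
  }
  p <- params
  fn <- function(tt) {
    u <- p$a * exp(-p$q * (tt - p$b)^p$n2 / p$c^2)
    saturate(u, "exp_filter")
  }
  wrap_image(apply_pointwise(m, fn, paper_loop))
}

#' Sinh-asinh-r intensity filter
#'
#' Pointwise transform `r = tt/eta`, `z = sinh(a1 * asinh(r + a2) * r^a3)`,
#' `u4 = z^a4`, with sign-preserving powers throughout (see
#' [sinh_asinh_params()]).  Never produces complex or non-finite values.
#'
#' @inheritParams exp_filter
#' @param params a [sinh_asinh_params()] record.
#' @return A [gray_image()] of filtered intensities.
#' @export
sinh_asinh_r_filter <- function(img, params = sinh_asinh_params(),
                                paper_loop = FALSE) {
  m <- check_image(img)
  if (!inherits(params, "sinh_asinh_params")) {
    stop("`params` must be created by sinh_asinh_params()", call. = FALSE)
  }
  p <- params
  fn <- function(tt) {
    r <- tt / p$eta
    z <- sinh(p$a1 * asinh(r + p$a2) * spow(r, p$a3))
    z <- saturate(z, "sinh_asinh_r_filter")
    saturate(spow(z, p$a4), "sinh_asinh_r_filter")
  }
  wrap_image(apply_pointwise(m, fn, paper_loop))
}

#' @export
print.filter_params <- function(x, ...) {
  cat("<", class(x)[1L], "> ",
      paste(names(x), unlist(x), sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize filter parameter records
#'
#' Parameter records round-trip through plain named lists so they can be
#' stored in YAML/JSON configuration blocks keyed by filter name.
#'
#' @param name one of `"exp"`, `"sinh_asinh_r"`, `"cosh_acosh"`,
#'   `"sech_asech"`.
#' @param values named list of overrides; unknown names are rejected.
#' @return The corresponding `filter_params` object.
#' @export
filter_params_from_list <- function(name, values = list()) {
  ctor <- switch(name,
    exp          = exp_params,
    sinh_asinh_r = sinh_asinh_params,
    cosh_acosh   = cosh_acosh_params,
    sech_asech   = sech_asech_params,
    stop("unknown filter name: ", name, call. = FALSE)
  )
  values <- as.list(values)
  known <- names(formals(ctor))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L) {
    stop("unknown parameter(s) for '", name, "' filter: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(ctor, values)
}
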