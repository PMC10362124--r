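# Internal 2D convolution machinery shared by the baseline operators and the
# phantom generators.  Border handling is symmetric reflection (edge pixel
# repeated), which avoids the spurious border responses of zero padding.
# Semantics are cross-correlation: out[i,j] = sum_{a,b} k[a,b] * img[i+a-cy-1,
# j+b-cx-1] with the anchor at (cy, cx) = (floor((kh-1)/2), floor((kw-1)/2)).

# Reflect-pad a matrix; pads must not exceed the matrix extent.
pad_reflect <- function(m, top, bottom, left, right) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(top <= h, bottom <= h, left <= w, right <= w)
  ri <- c(rev(seq_len(top)), seq_len(h), h + 1L - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(w), w + 1L - seq_len(right))
  m[ri, ci, drop = FALSE]
}

# Same-size cross-correlation with reflective borders.  Small kernels use
# direct shift-accumulate; larger ones switch to an FFT product on the padded
# grid (identical result up to round-off).
conv2_reflect <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  cy <- (kh - 1L) %/% 2L; cx <- (kw - 1L) %/% 2L
  p <- pad_reflect(img, cy, kh - 1L - cy, cx, kw - 1L - cx)
  h <- nrow(img); w <- ncol(img)
  if (kh * kw <= 121L) {
    out <- matrix(0, h, w)
    for (a in seq_len(kh)) {
      for (b in seq_len(kw)) {
        k <- kernel[a, b]
        if (k != 0) {
          out <- out + k * p[(a - 1L) + seq_len(h), (b - 1L) + seq_len(w)]
        }
      }
    }
    return(out)
  }
  ph <- nrow(p); pw <- ncol(p)
  K <- matrix(0, ph, pw)
  K[seq_len(kh), seq_len(kw)] <- kernel
  res <- stats::fft(Conj(stats::fft(K)) * stats::fft(p), inverse = TRUE)
  Re(res)[seq_len(h), seq_len(w)] / (ph * pw)
}

# Normalised 1D Gaussian kernel, radius 3*sigma (at least 1).
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with reflective borders; sigma = 0 is the identity.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  img <- conv2_reflect(img, matrix(k, ncol = 1L))
  conv2_reflect(img, matrix(k, nrow = 1L))
}
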