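# Independent scalar reference implementations used as oracles.  These stay
# deliberately naive (plain per-pixel loops, recurrence evaluation) and never
# call the vectorized package code paths they check.

ref_exp_filter <- function(img, a, q, b, n2, cc) {
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      out[i, j] <- a * exp(-q * (img[i, j] - b)^n2 / cc^2)
    }
  }
  out
}

ref_sinh_filter <- function(img, eta, a1, a2, a3, a4) {
  sp <- function(x, p) sign(x) * abs(x)^p
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      r <- img[i, j] / eta
      z <- sinh(a1 * asinh(r + a2) * sp(r, a3))
      out[i, j] <- sp(z, a4)
    }
  }
  out
}

# Chebyshev polynomial T_N by the three-term recurrence.
ref_chebyshev_T <- function(N, u) {
  t0 <- rep(1, length(u))
  if (N == 0) return(t0)
  t1 <- u
  if (N == 1) return(t1)
  for (k in 2:N) {
    t2 <- 2 * u * t1 - t0
    t0 <- t1
    t1 <- t2
  }
  t1
}

# Count sign changes of the successive differences of a profile (its
# discrete derivative), ignoring exact zeros.
n_derivative_sign_changes <- function(y) {
  d <- diff(y)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(diff(sign(d)) != 0)
}

random_image <- function(h, w, seed) {
  withr::with_seed(seed, gray_image(matrix(stats::runif(h * w), h, w)))
}

# Reduce a classed/attributed matrix to a bare numeric matrix for comparison.
strip_mat <- function(m) {
  m <- unclass(m)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# 180-degree rotation about the centred origin: index i0 -> (2c - i0) mod n
# (0-based).  Real inverse transforms require H to be invariant under this.
rotate180_centered <- function(H) {
  H <- strip_mat(H)
  h <- nrow(H); w <- ncol(H)
  ri <- ((2L * (h %/% 2L) - (seq_len(h) - 1L)) %% h) + 1L
  ci <- ((2L * (w %/% 2L) - (seq_len(w) - 1L)) %% w) + 1L
  H[ri, ci]
}
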