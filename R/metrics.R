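#' Peak signal-to-noise ratio for unit-range images
#'
#' `10 * log10(1 / MSE)` for images on the \[0, 1\] scale.  Identical images
#' (zero MSE) return the capped sentinel 99 dB, which is also the overall
#' cap.
#'
#' @param reference,test [gray_image()]s or numeric matrices of equal shape.
#' @return PSNR in decibels (scalar).
#' @examples
#' a <- matrix(0, 8, 8); b <- matrix(0.1, 8, 8)
#' psnr(a, b) # MSE 0.01 -> 20 dB
#' @export
psnr <- function(reference, test) {
  r <- check_image(reference, "reference")
  t <- check_image(test, "test")
  if (!identical(dim(r), dim(t))) {
    stop("`reference` and `test` must have equal shapes", call. = FALSE)
  }
  mse <- mean((r - t)^2)
  if (mse == 0) return(99)
  min(10 * log10(1 / mse), 99)
}

#' Boundary precision/recall/F1 within a pixel tolerance
#'
#' Scores a predicted binary edge mask against ground truth: a predicted
#' pixel is a true positive iff an *unmatched* truth pixel lies within
#' Chebyshev (chessboard) distance `tolerance_px`; matching is greedy in scan
#' order, without replacement, so over-prediction cannot inflate precision.
#' `precision = matches / #predicted`, `recall = matches / #truth`, and
#' `f1 = 0` when `precision + recall = 0` (declared convention, covering the
#' empty cases).
#'
#' @param predicted,truth logical matrices of equal shape.
#' @param tolerance_px match radius in pixels, `>= 0` (default 1).
#' @return An object of class `"edge_score"`: list with `precision`,
#'   `recall`, `f1`, `tolerance_px`, `matches`.
#' @examples
#' truth <- matrix(FALSE, 16, 16); truth[10, 10] <- TRUE
#' pred <- matrix(FALSE, 16, 16); pred[11, 11] <- TRUE
#' edge_f1(pred, truth, tolerance_px = 1)$f1 # 1
#' edge_f1(pred, truth, tolerance_px = 0)$f1 # 0
#' @export
edge_f1 <- function(predicted, truth, tolerance_px = 1L) {
  if (!identical(dim(predicted), dim(truth))) {
    stop("`predicted` and `truth` must have equal shapes", call. = FALSE)
  }
  if (tolerance_px < 0) stop("`tolerance_px` must be >= 0", call. = FALSE)
  predicted <- predicted != 0
  truth <- truth != 0
  np <- sum(predicted); nt <- sum(truth)
  h <- nrow(truth); w <- ncol(truth)
  tol <- as.integer(tolerance_px)
  available <- truth
  matches <- 0L
  if (np > 0L && nt > 0L) {
    idx <- which(predicted)
    pi_ <- ((idx - 1L) %% h) + 1L
    pj_ <- ((idx - 1L) %/% h) + 1L
    for (k in seq_along(idx)) {
      i <- pi_[k]; j <- pj_[k]
      ri <- max(1L, i - tol):min(h, i + tol)
      rj <- max(1L, j - tol):min(w, j + tol)
      win <- available[ri, rj, drop = FALSE]
      hit <- which(win)[1L]
      if (!is.na(hit)) {
        wi <- ((hit - 1L) %% length(ri)) + 1L
        wj <- ((hit - 1L) %/% length(ri)) + 1L
        available[ri[wi], rj[wj]] <- FALSE
        matches <- matches + 1L
      }
    }
  }
  precision <- if (np > 0L) matches / np else 0
  recall <- if (nt > 0L) matches / nt else 0
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tolerance_px = tol, matches = matches),
            class = "edge_score")
}

#' @export
print.edge_score <- function(x, ...) {
  cat(sprintf(
    "<edge_score> precision %.3f, recall %.3f, F1 %.3f (tolerance %d px)\n",
    x$precision, x$recall, x$f1, x$tolerance_px))
  invisible(x)
}

#' Mean brightness of an image
#'
#' The arithmetic mean of all pixels — the quantitative handle on the
#' odd/even progression-parity effect of the exp filter (odd `n2` brightens,
#' even `n2` darkens).
#'
#' @param img a [gray_image()] or numeric matrix (any size).
#' @return Scalar mean intensity.
#' @export
mean_brightness <- function(img) {
  if (!is.numeric(img)) stop("`img` must be numeric", call. = FALSE)
  if (any(!is.finite(img))) {
    stop("`img` contains non-finite pixels", call. = FALSE)
  }
  mean(img)
}

#' Binarise an enhanced image for edge scoring
#'
#' Filter outputs are grayscale enhancements on an arbitrary scale; to
#' compare them with edge operators on equal footing they are rescaled to
#' \[0, 1\] ([rescale_for_display()]) and thresholded with the same rule as
#' the baselines (strict `>`; `"auto"` = mean + 1 sd).
#'
#' @param img a [gray_image()] or numeric matrix (any scale).
#' @param threshold scalar on the rescaled \[0, 1\] scale, or `"auto"`.
#' @return A logical matrix.
#' @export
binarize_enhanced <- function(img, threshold = "auto") {
  m <- unclass(rescale_for_display(img))
  m > resolve_threshold(m, threshold)
}
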