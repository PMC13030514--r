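#' Moving-average spectral smoothing
#'
#' Centred moving average with an odd window. At the spectrum edges the window
#' shrinks symmetrically-truncated to the available bands, so output length
#' equals input length and a constant spectrum is unchanged. `window = 1` is
#' the identity. The operator is linear in its input.
#'
#' @param x Numeric spectrum, or a matrix with one spectrum per row.
#' @param window Odd integer window width (bands), `window <= length`.
#' @return Smoothed object of the same shape.
#' @examples
#' moving_average(c(1, 2, 3, 4), 3)  # 1.5 2 3 3.5
#' @export
moving_average <- function(x, window = 5) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (is.matrix(x)) {
    return(t(apply(x, 1, moving_average, window = window)))
  }
  n <- length(x)
  if (window > n) stop("window exceeds spectrum length", call. = FALSE)
  if (window == 1) return(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Standard normal variate (SNV) transformation
#'
#' Per-spectrum standardisation: subtract the spectrum mean and divide by its
#' population (divisor-`n`) standard deviation. Corrects multiplicative
#' scatter and additive baseline shifts: `snv(a*x + b) = snv(x)` for `a > 0`,
#' and the transform is idempotent. Output has mean 0 and population sd 1.
#'
#' @param x Numeric spectrum (>= 2 bands, non-zero spread), or a matrix with
#'   one spectrum per row.
#' @return Transformed object of the same shape.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, snv)))
  }
  if (length(x) < 2) stop("SNV needs at least 2 bands", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("SNV undefined for a zero-spread spectrum", call. = FALSE)
  (x - m) / s
}

#' Standard preprocessing chain for ROI spectra
#'
#' Applies moving-average smoothing first, then SNV — in that fixed order.
#' No band trimming is performed; the full wavelength range is retained
#' (any band-window restriction happens later, inside the spectral metrics).
#'
#' @param x Spectrum vector or matrix (rows = spectra).
#' @param window Smoothing window (odd; default 5 bands).
#' @param snv_enabled Apply SNV after smoothing (default `TRUE`).
#' @return Preprocessed object of the same shape.
#' @export
preprocess_spectra <- function(x, window = 5, snv_enabled = TRUE) {
  out <- moving_average(x, window = window)
  if (snv_enabled) out <- snv(out)
  out
}
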