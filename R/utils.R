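#' @useDynLib tubelattice, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft kmeans rnorm runif sd var quantile
#' @importFrom utils head
NULL

stop_tl <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tubelattice_error")))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_tl(paste0(what, " must be finite"), "tl_invalid_argument")
  invisible(x)
}

#' FFT sample frequencies for one axis
#'
#' Returns frequencies in cycles per Angstrom in standard FFT order
#' (0, 1, ..., n/2-1, -n/2, ..., -1) / (n * pixel_size).
#'
#' @param n number of samples.
#' @param pixel_size sampling step in Angstrom.
#' @keywords internal
fft_freq <- function(n, pixel_size = 1) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / (n * pixel_size)
}

#' Radial frequency grid of an n x n image (cycles/Angstrom)
#' @keywords internal
freq_grid2d <- function(n, pixel_size = 1) {
  f <- fft_freq(n, pixel_size)
  sqrt(outer(f^2, f^2, "+"))
}

#' Translate an image by a (possibly fractional) pixel shift
#'
#' Fourier shift: the content moves by `+shift`, i.e. `out(u) = in(u - shift)`,
#' with periodic wrap-around.
#'
#' @param img numeric matrix.
#' @param shift length-2 numeric, pixels (x, y).
#' @return shifted matrix.
#' @export
fourier_shift <- function(img, shift) {
  check_finite(shift, "shift")
  n <- nrow(img); m <- ncol(img)
  fx <- fft_freq(n); fy <- fft_freq(m)
  ph <- exp(-2i * pi * (outer(fx * shift[1], fy * shift[2], "+")))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (n * m)
}

#' Gaussian band-pass filter an image
#'
#' @param img numeric matrix.
#' @param pixel_size Angstrom per pixel.
#' @param low,high resolution limits in Angstrom (`low` suppresses features
#'   coarser than this; `high` features finer). `NULL` disables one side.
#' @return filtered matrix.
#' @export
bandpass_filter <- function(img, pixel_size, low = NULL, high = NULL) {
  n <- nrow(img)
  fr <- freq_grid2d(n, pixel_size)
  h <- matrix(1, n, n)
  if (!is.null(high)) h <- h * exp(-(fr * high)^2 / 2)
  if (!is.null(low)) h <- h * (1 - exp(-(fr * low)^2 / 2))
  Re(fft(fft(img) * h, inverse = TRUE)) / (n * n)
}

#' Normalized cross-correlation of two arrays
#' @keywords internal
ncc <- function(a, b) {
  a <- as.vector(a) - mean(a); b <- as.vector(b) - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Downsample an image by integer block averaging
#' @keywords internal
downsample_image <- function(img, factor) {
  n <- nrow(img) %/% factor * factor
  img <- img[seq_len(n), seq_len(n), drop = FALSE]
  idx <- rep(seq_len(n %/% factor), each = factor)
  t(rowsum(t(rowsum(img, idx)), idx)) / factor^2
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
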