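# Independent oracles and small fixtures shared across tests.

# Inverse Abel transform of an across-tube projection profile:
# f(r) = -(1/pi) * integral_r^Inf p'(x) / sqrt(x^2 - r^2) dx.
# p: profile sampled at x = (i - c0) * ps; returns f on r = 0..rmax voxels.
abel_inverse <- function(p, ps, rmax) {
  n <- length(p)
  c0 <- n / 2 + 1
  x <- (seq_len(n) - c0) * ps
  # symmetrize and keep the right half
  half <- (p + rev(p)) / 2
  xr <- x[x >= 0]
  pr <- half[x >= 0]
  dp <- c(diff(pr) / diff(xr), 0)
  f <- numeric(rmax + 1)
  for (k in 0:rmax) {
    r <- k * ps
    integrand <- function(xx) {
      d <- approx(xr[-length(xr)] + diff(xr) / 2, dp[-length(dp)], xx,
                  rule = 2)$y
      d / sqrt(pmax(xx^2 - r^2, 1e-9))
    }
    xs <- seq(r + ps / 20, max(xr) - ps, length.out = 400)
    f[k + 1] <- -(1 / pi) * pracma::trapz(xs, integrand(xs))
  }
  f
}

# Default desk-scale objects used by many tests.
tl_spec <- function(...) tube_lattice_spec(...)
tl_optics <- function(...) optics_params(...)

# Small phantom: a few Gaussian blobs in a box, deterministic.
make_phantom <- function(n = 48, ps = 4) {
  v <- array(0, dim = rep(n, 3))
  blobs <- rbind(c(20, -28, 8, 1.0), c(-32, 12, -20, 0.8),
                 c(0, 0, 0, 1.2), c(36, 30, 24, 0.6))
  buf <- as.numeric(v)
  # 6 A blobs keep spectral power through the resolution band the
  # reconstruction tests probe
  for (i in seq_len(nrow(blobs)))
    tubelattice:::add_blob(buf, n, blobs[i, 1:3], 6, blobs[i, 4], ps)
  density_volume(array(buf, dim = rep(n, 3)), ps)
}

# Axial autocorrelation of an image along y at integer lags, normalized.
axial_autocorr <- function(img, rows = seq_len(nrow(img))) {
  p <- colMeans(img[rows, , drop = FALSE])
  p <- p - mean(p)
  ac <- Re(fft(Mod(fft(p))^2, inverse = TRUE))
  ac / ac[1]
}
ncc <- function(a, b) tubelattice:::ncc(a, b)
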