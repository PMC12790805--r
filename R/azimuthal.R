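#' Azimuthal-average initial model
#'
#' Backprojects aligned tube particles at random azimuths and averages the
#' result along the tube axis, yielding a featureless, cylindrically
#' symmetric initial model: the two leaflet shells survive, the protein
#' lattice smears into a continuous annulus, and no high-resolution protein
#' features remain to bias later refinement.
#'
#' @param stack an [image_stack()].
#' @param records aligned records (`psi`, `sx`, `sy` from
#'   [align_tube_stack()]); unless `assign = FALSE`, `rot` is reassigned
#'   uniformly on [0, 360) and `tilt` to 90 or 270 equiprobably from `seed`
#'   (use [assign_random_orientations()] first to keep the assignment).
#' @param seed RNG seed for the random azimuth assignment.
#' @param assign reassign `rot`/`tilt` internally.
#' @param ctf_mode,optics passed to [reconstruct_backproject()].
#' @param max_particles cap on the number of particles backprojected; the
#'   average is strongly self-averaging, so a few hundred suffice.
#' @param lowpass Gaussian low-pass (Angstrom) applied to the final map;
#'   the azimuthal average is a deliberately low-resolution model, and the
#'   filter suppresses the angular-sampling streaks that ramp-weighted
#'   backprojection leaves at high frequency.
#' @param symmetrize additionally replace the map by its exact azimuthal
#'   average: at desk-scale particle counts the random-azimuth
#'   backprojection alone leaves a few-percent angular ripple from finite
#'   angle sampling, which the symmetrization removes (the model is meant
#'   to be featureless).
#' @return a [density_volume()].
#' @export
azimuthal_average <- function(stack, records, seed = 1, assign = TRUE,
                              ctf_mode = "none", optics = NULL,
                              max_particles = 400, lowpass = 12,
                              symmetrize = TRUE) {
  keep <- which(is.finite(records$psi))
  if (!length(keep)) stop_tl("no aligned particles", "tl_invalid_argument")
  if (length(keep) > max_particles) keep <- keep[seq_len(max_particles)]
  recs <- records[keep, , drop = FALSE]
  sub <- image_stack(stack$data[, , keep, drop = FALSE], stack$pixel_size)
  if (assign) recs <- assign_random_orientations(recs, seed)
  vol <- reconstruct_backproject(sub, recs, ctf_mode = ctf_mode, optics = optics)
  zmean <- apply(vol$data, c(1, 2), mean)
  if (!is.null(lowpass))
    zmean <- bandpass_filter(zmean, vol$pixel_size, high = lowpass)
  if (symmetrize) {
    n <- nrow(zmean)
    ax <- seq_len(n) - (n / 2 + 1)
    rr <- sqrt(outer(ax^2, ax^2, "+"))
    rb <- round(rr * 2) / 2                       # half-voxel annuli
    prof <- rowsum(as.vector(zmean), as.vector(rb))
    cnt <- rowsum(rep(1, length(rb)), as.vector(rb))
    vals <- as.numeric(rownames(prof))
    zmean <- matrix(approx(vals, prof / cnt, xout = as.vector(rr),
                           rule = 2)$y, n, n)
  }
  density_volume(array(zmean, dim = dim(vol$data)), vol$pixel_size)
}

#' Assign random tube azimuths and polarities to aligned records
#'
#' The azimuth about the tube axis is unobservable before refinement, so
#' `rot` is drawn stratified-uniform on [0, 360) (a shuffled regular grid
#' with sub-cell jitter: marginally uniform, but with far lower angular
#' clumping than independent draws, which keeps the azimuthal average
#' self-averaging at desk-scale particle counts) and `tilt` from
#' \{90, 270\} equiprobably; `psi` and shifts are left untouched.
#'
#' @param records particle records.
#' @param seed RNG seed.
#' @return updated records.
#' @export
assign_random_orientations <- function(records, seed = 1) {
  with_seed(seed, {
    m <- nrow(records)
    records$rot <- (sample(seq_len(m)) - 1 + runif(m)) * 360 / m
    records$tilt <- sample(c(90, 270), m, replace = TRUE)
  })
  records
}

#' Radial density profile about the tube (z) axis
#'
#' Mean density in cylindrical annuli of one-voxel width.
#'
#' @param volume a [density_volume()].
#' @return data frame with `radius` (Angstrom, annulus center) and `density`.
#' @export
radial_profile <- function(volume) {
  n <- dim(volume$data)[1]
  ax <- seq_len(n) - (n / 2 + 1)
  ridx <- round(sqrt(outer(ax^2, ax^2, "+")))
  zmean <- apply(volume$data, c(1, 2), mean)
  rmax <- n / 2 - 1
  dens <- vapply(0:rmax, function(k) mean(zmean[ridx == k]), numeric(1))
  data.frame(radius = (0:rmax) * volume$pixel_size, density = dens)
}

#' Azimuthal power fraction within a radial band
#'
#' Fraction of the band's angular Fourier power in non-zero orders; small
#' values mean the volume is nearly cylindrically symmetric there.  Used to
#' verify that an azimuthal average contains no residual protein features.
#'
#' @param volume a [density_volume()].
#' @param r_min,r_max radial band, Angstrom.
#' @param n_theta angular samples.
#' @return scalar in [0, 1].
#' @export
azimuthal_power_fraction <- function(volume, r_min, r_max, n_theta = 120) {
  n <- dim(volume$data)[1]
  ps <- volume$pixel_size
  c0 <- n / 2 + 1
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  radii <- seq(r_min, r_max, by = ps)
  zmid <- (n / 4):(3 * n / 4)
  pw0 <- pwk <- 0
  for (iz in zmid) {
    sl <- volume$data[, , iz]
    for (r in radii) {
      xs <- r / ps * cos(theta) + c0
      ys <- r / ps * sin(theta) + c0
      ring <- bilinear_sample(sl, xs, ys)
      co <- fft(ring)
      pw0 <- pw0 + Mod(co[1])^2
      pwk <- pwk + sum(Mod(co[-1])^2)
    }
  }
  pwk / (pw0 + pwk)
}

# bilinear sampling of a matrix at fractional 1-based coordinates
bilinear_sample <- function(m, xs, ys) {
  n <- nrow(m); mm <- ncol(m)
  xs <- pmin(pmax(xs, 1), n - 1e-9); ys <- pmin(pmax(ys, 1), mm - 1e-9)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) + m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy + m[cbind(x0 + 1, y0 + 1)] * fx * fy
}
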