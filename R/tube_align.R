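#' Per-particle tube alignment and diameter analysis
#'
#' A tube crossing the box collapses, once rotated vertical, onto a 1D
#' across-tube profile whose variance is maximal at the correct in-plane
#' angle and whose outer membrane peaks locate the tube axis and diameter.
#'
#' @name tube_align
NULL

# Local maxima of a 1D profile with parabolic sub-pixel refinement.
# Returns data frame pos (1-based, fractional), height.
profile_peaks <- function(p) {
  n <- length(p)
  i <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1
  if (!length(i)) return(data.frame(pos = numeric(), height = numeric()))
  denom <- p[i - 1] - 2 * p[i] + p[i + 1]
  off <- ifelse(denom < 0, 0.5 * (p[i - 1] - p[i + 1]) / denom, 0)
  data.frame(pos = i + off, height = p[i] - 0.25 * (p[i - 1] - p[i + 1]) * off)
}

# Outermost sufficiently high symmetric peak pair about a provisional axis.
# Returns list(left, right, axis) in profile coordinates or NULL.
leaflet_peak_pair <- function(prof, min_frac = 0.5) {
  pk <- profile_peaks(prof)
  if (nrow(pk) < 2) return(NULL)
  pk <- pk[pk$height >= min_frac * max(pk$height), , drop = FALSE]
  if (nrow(pk) < 2) return(NULL)
  axis0 <- sum(seq_along(prof) * pmax(prof, 0)) / sum(pmax(prof, 0))
  left <- pk[pk$pos < axis0, , drop = FALSE]
  right <- pk[pk$pos > axis0, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(NULL)
  l <- left[which.min(left$pos), ]
  r <- right[which.max(right$pos), ]
  list(left = l$pos, right = r$pos, axis = (l$pos + r$pos) / 2)
}

#' Estimate the in-plane angle and across-tube shift of a tube image
#'
#' Scans in-plane angles on a 1-degree grid (the across-tube profile is
#' computed by collapsing the image along the candidate tube direction),
#' picks the angle maximizing the profile variance, refines it
#' parabolically, and locates the tube axis at the symmetric midpoint of the
#' two outermost membrane peaks.  The returned shift is the across-tube
#' offset vector in image pixels (the along-tube component is unobservable
#' and set to zero).  The 180-degree ambiguity in psi is left unresolved.
#'
#' @param image numeric matrix (one tube crossing the box).
#' @param angle_step search grid, degrees.
#' @param score_floor minimum ratio of best to median profile variance below
#'   which no tube is declared.
#' @return list with `psi` (degrees, in [0, 180)), `shift` (length-2
#'   pixels), `score` (best/median profile-variance ratio) and `axis_offset`
#'   (signed across-tube axis offset, pixels).
#' @export
estimate_psi_shift <- function(image, angle_step = 1, score_floor = 2) {
  # coarse scan, then the 1-degree grid around the coarse optimum
  coarse <- seq(0, 179, by = 4)
  vr_c <- apply(cpp_tube_profiles(image, coarse), 2, var)
  score <- max(vr_c) / stats::median(vr_c)
  if (!is.finite(score) || score < score_floor)
    stop_tl("no tube detected (profile variance below floor)", "tl_no_tube")
  a0 <- coarse[which.max(vr_c)]
  angs <- (seq(a0 - 5, a0 + 5, by = angle_step)) %% 180
  prof <- cpp_tube_profiles(image, angs)
  vr <- apply(prof, 2, var)
  k <- which.max(vr)
  da <- if (k == 1 || k == length(vr)) 0 else {
    denom <- vr[k - 1] - 2 * vr[k] + vr[k + 1]
    if (denom < 0) 0.5 * (vr[k - 1] - vr[k + 1]) / denom * angle_step else 0
  }
  a_best <- (angs[k] + da) %% 180
  p_best <- cpp_tube_profiles(image, a_best)[, 1]
  pair <- leaflet_peak_pair(p_best)
  n <- nrow(image)
  d <- if (is.null(pair)) 0 else pair$axis - (n / 2 + 1)
  u <- c(cos(deg2rad(a_best)), sin(deg2rad(a_best)))
  list(psi = (a_best - 90) %% 180, shift = d * u, score = score,
       axis_offset = d)
}

#' Measure the tube diameter by membrane peak detection
#'
#' Rotates the tube vertical using `psi`, averages along the axis, and takes
#' the separation of the outermost symmetric membrane peaks (sub-pixel by
#' parabolic interpolation) times the pixel size.  With a double-shell
#' bilayer this is the outer-leaflet diameter.
#'
#' The projection of a radius-R shell of Gaussian cross-section peaks
#' slightly inside R (the Abel-projection singularity at the tangent is
#' pulled inward by the smearing).  When `shell_sd` is supplied, the
#' measured peak separation is corrected for this known bias by inverting
#' the forward model, so the returned value estimates the true shell
#' diameter; without it the raw peak separation is returned.
#'
#' @param image numeric matrix.
#' @param psi in-plane angle, degrees (from [estimate_psi_shift()]).
#' @param pixel_size Angstrom per pixel.
#' @param shell_sd Gaussian cross-section sd of the membrane shell,
#'   Angstrom, for peak-bias correction (optional).
#' @param transfer optional imaging transfer function `f(freq)` (e.g. the
#'   magnitude of the CTF for phase-flipped images), folded into the
#'   peak-bias correction.
#' @return diameter in Angstrom.
#' @export
measure_diameter <- function(image, psi, pixel_size, shell_sd = NULL,
                             transfer = NULL) {
  prof <- cpp_tube_profiles(image, (psi + 90) %% 180)[, 1]
  pair <- leaflet_peak_pair(prof)
  if (is.null(pair))
    stop_tl("diameter measurement failed: fewer than two membrane peaks",
            "tl_measurement_failed")
  sep <- (pair$right - pair$left) * pixel_size
  if (is.null(shell_sd)) return(sep)
  2 * shell_radius_from_peak(sep / 2, shell_sd, transfer)
}

#' Projected-peak position of a Gaussian tube shell
#'
#' Position of the maximum of the across-tube projection of a cylindrical
#' shell of radius `R` with Gaussian cross-section `sigma`; always slightly
#' inside `R`.  `shell_radius_from_peak` inverts the relation.
#'
#' @param R shell radius, Angstrom.
#' @param sigma shell cross-section sd, Angstrom.
#' @return peak position (or inverted radius), Angstrom.
#' @export
shell_peak_position <- function(R, sigma, transfer = NULL) {
  if (is.null(transfer)) {
    t <- seq(0, R + 6 * sigma, length.out = 600)
    xs <- seq(max(R - 4 * sigma, 0), R + 2 * sigma, length.out = 241)
    p <- vapply(xs, function(x)
      sum(exp(-(sqrt(x^2 + t^2) - R)^2 / (2 * sigma^2))), numeric(1))
    i <- which.max(p)
    if (i == 1 || i == length(p)) return(xs[i])
    den <- p[i - 1] - 2 * p[i] + p[i + 1]
    return(xs[i] + 0.5 * (p[i - 1] - p[i + 1]) / den * (xs[2] - xs[1]))
  }
  # with an imaging transfer function: the axial average of a filtered
  # image is the 1D convolution of the true profile with the transfer's
  # fy = 0 line, so the predicted peak is found on the filtered profile
  L <- 2048
  xs <- (seq_len(L) - L / 2 - 1)              # 1 A sampling, centered
  t <- seq(0, R + 6 * sigma, length.out = 600)
  prof <- vapply(xs, function(x)
    sum(exp(-(pmax(sqrt(x^2 + t^2), 0) - R)^2 / (2 * sigma^2))), numeric(1))
  fr <- fft_freq(L, 1)
  filt <- transfer(abs(fr))
  pf <- Re(fft(fft(prof) * filt, inverse = TRUE)) / L
  half <- pf[xs >= max(R - 4 * sigma, 0) & xs <= R + 3 * sigma]
  xh <- xs[xs >= max(R - 4 * sigma, 0) & xs <= R + 3 * sigma]
  i <- which.max(half)
  if (i == 1 || i == length(half)) return(xh[i])
  den <- half[i - 1] - 2 * half[i] + half[i + 1]
  xh[i] + 0.5 * (half[i - 1] - half[i + 1]) / den
}

#' @rdname shell_peak_position
#' @param x_peak observed projected-peak position, Angstrom.
#' @param transfer optional imaging transfer function `f(freq)` applied to
#'   the model profile before peak finding.
#' @export
shell_radius_from_peak <- function(x_peak, sigma, transfer = NULL) {
  f <- function(R) shell_peak_position(R, sigma, transfer) - x_peak
  stats::uniroot(f, c(x_peak - 2 * sigma, x_peak + 5 * sigma),
                 extendInt = "yes", tol = 1e-3)$root
}

#' Align a stack of tube particles
#'
#' Runs [estimate_psi_shift()] and [measure_diameter()] on every image and
#' fills the `psi`, `sx`, `sy` record columns (tilt/rot untouched) plus a
#' `tl_diameter_meas` column.  Particles where no tube is detected get
#' `NA` measurements.
#'
#' @param stack an [image_stack()].
#' @param records particle records (one row per image).
#' @param optics an [optics_params()]; when given together with per-record
#'   defocus, images are CTF phase-flipped before the diameter measurement
#'   (raw cryo-EM contrast is inverted, so peak detection needs corrected
#'   polarity; the angle estimate is contrast-sign-invariant).
#' @param shell_sd membrane shell sd for diameter peak-bias correction
#'   (see [measure_diameter()]).
#' @return updated records.
#' @export
align_tube_stack <- function(stack, records, optics = NULL, shell_sd = NULL) {
  m <- n_images(stack)
  psi <- dia <- score <- rep(NA_real_, m)
  sx <- sy <- rep(0, m)
  for (i in seq_len(m)) {
    img <- get_image(stack, i)
    est <- tryCatch(estimate_psi_shift(img),
                    tubelattice_error = function(e) NULL)
    if (is.null(est)) next
    psi[i] <- est$psi; sx[i] <- est$shift[1]; sy[i] <- est$shift[2]
    score[i] <- est$score
    if (!is.null(optics) && !is.null(records$defocus) &&
        is.finite(records$defocus[i]))
      img <- ctf_phase_flip(img, optics, records$defocus[i])
    dia[i] <- tryCatch(measure_diameter(img, est$psi, stack$pixel_size,
                                        shell_sd = shell_sd),
                       tubelattice_error = function(e) NA_real_)
  }
  records$psi <- psi
  records$sx <- sx
  records$sy <- sy
  records$tl_align_score <- score
  records$tl_diameter_meas <- dia
  records
}

#' Histogram tube diameters and select the major bin
#'
#' Bins the measured diameters (default 20 bins across the observed range)
#' and returns the particles falling in the modal bin; ties go to the
#' lower-diameter bin.
#'
#' @param diameters numeric vector, Angstrom (NA allowed).
#' @param bin_width bin width in Angstrom; overrides `n_bins`.
#' @param n_bins number of bins when `bin_width` is not given.
#' @return object of class `diameter_histogram`: list with `bin_edges`,
#'   `counts`, `major_bin` and `selected` (indices into `diameters`).
#' @export
select_major_diameter_bin <- function(diameters, bin_width = NULL, n_bins = 20) {
  ok <- which(is.finite(diameters))
  if (!length(ok)) stop_tl("no finite diameters", "tl_invalid_argument")
  d <- diameters[ok]
  lo <- min(d); hi <- max(d)
  edges <- if (!is.null(bin_width)) {
    seq(lo, hi + bin_width, by = bin_width)
  } else if (hi > lo) {
    seq(lo, hi, length.out = n_bins + 1)
  } else c(lo, lo + 1)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), length(edges) - 1)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  major <- which.max(counts)           # which.max takes the lowest tie
  structure(list(bin_edges = edges, counts = counts, major_bin = major,
                 selected = ok[bin == major]),
            class = "diameter_histogram")
}

#' @export
print.diameter_histogram <- function(x, ...) {
  cat(sprintf("diameter_histogram: %d bins, major bin %d (%.1f-%.1f A), %d particles\n",
              length(x$counts), x$major_bin, x$bin_edges[x$major_bin],
              x$bin_edges[x$major_bin + 1], x$counts[x$major_bin]))
  invisible(x)
}
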