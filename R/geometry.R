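#' Rotation, projection and backprojection conventions
#'
#' This file is the single source of truth for the package's Euler-angle,
#' shift and indexing semantics.  Every other module builds on it.
#'
#' Conventions:
#' * Euler triplet `(rot, tilt, psi)` in degrees, intrinsic ZYZ:
#'   `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`.  `rot` is the azimuth about
#'   the tube axis (a.k.a. phi), `tilt` the out-of-plane angle (theta),
#'   `psi` the in-plane angle.  Angles are stored normalized to [0, 360).
#' * Volumes are cubic `n x n x n` arrays (`n` even), voxel centers at
#'   integer indices, box center at 1-based index `n/2 + 1`; the tube axis
#'   runs along z.
#' * Images are `n x n` matrices with x as the first (row) index.
#' * Shifts are in pixels and applied after projection: the projected image
#'   is translated by `+shift`, so a volume point `p` (Angstrom, centered)
#'   appears at pixel position `(R p)_xy / pixel_size + shift` relative to
#'   the box center.
#' * A tilt of 270 degrees views the tube with opposite polarity:
#'   `R(rot, 270, psi) = diag(1, -1, -1) %*% R(rot, 90, 180 - psi)`, i.e.
#'   the 270-degree projection equals the (180 - psi), tilt-90 projection
#'   mirrored in y.
#'
#' @name geometry-conventions
#' @keywords internal
NULL

#' Construct an Euler triplet
#'
#' @param rot,tilt,psi angles in degrees; normalized to [0, 360).
#' @return named numeric vector of class `euler`.
#' @export
euler <- function(rot = 0, tilt = 0, psi = 0) {
  ang <- c(rot = as.numeric(rot), tilt = as.numeric(tilt), psi = as.numeric(psi))
  check_finite(ang, "Euler angles")
  structure(ang %% 360, class = "euler")
}

#' Rotation matrix for an Euler triplet (intrinsic ZYZ)
#'
#' `R = Rz(psi) Ry(tilt) Rz(rot)`, right-handed.  A volume-frame point `p`
#' appears in the projection at the (x, y) components of `R p`.
#'
#' @param e an [euler()] triplet or length-3 numeric `(rot, tilt, psi)`.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(e) {
  if (!inherits(e, "euler")) e <- euler(e[1], e[2], e[3])
  rz <- function(a) {
    a <- deg2rad(a)
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- deg2rad(a)
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(e[["psi"]]) %*% ry(e[["tilt"]]) %*% rz(e[["rot"]])
}

#' Normalize a tilt of 270 degrees to the canonical tilt-90 grid
#'
#' Returns the equivalent viewing direction on the tilt-90 grid together with
#' a `mirror_y` flag: the tilt-270 projection equals the returned triplet's
#' projection mirrored in y (opposite polarity).
#'
#' @param e an [euler()] triplet.
#' @return list with `euler` and `mirror_y`.
#' @export
normalize_tilt <- function(e) {
  if (!inherits(e, "euler")) e <- euler(e[1], e[2], e[3])
  if (abs(e[["tilt"]] - 270) < 1e-9) {
    list(euler = euler(e[["rot"]], 90, 180 - e[["psi"]]), mirror_y = TRUE)
  } else {
    list(euler = e, mirror_y = FALSE)
  }
}

#' Cubic density volume with physical pixel size
#'
#' @param data `n x n x n` numeric array (`n` even) or a single `n` to create
#'   an empty volume.
#' @param pixel_size Angstrom per voxel.
#' @return object of class `density_volume`: list with `data` and `pixel_size`.
#' @export
density_volume <- function(data, pixel_size) {
  if (length(data) == 1 && is.numeric(data)) data <- array(0, dim = rep(data, 3))
  d <- dim(data)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop_tl("volume must be a cubic array", "tl_invalid_argument")
  if (d[1] %% 2 != 0) stop_tl("volume side must be even", "tl_invalid_argument")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_tl("pixel_size must be positive", "tl_invalid_argument")
  structure(list(data = data, pixel_size = pixel_size), class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("density_volume: %d^3 voxels, %.3g A/voxel (%.0f A box)\n",
              n, x$pixel_size, n * x$pixel_size))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

#' Image stack
#'
#' @param data `n x n x m` array of m images, or a single image matrix.
#' @param pixel_size Angstrom per pixel.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  structure(list(data = data, pixel_size = pixel_size), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d images of %d x %d px, %.3g A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

n_images <- function(stack) dim(stack$data)[3]
get_image <- function(stack, i) stack$data[, , i]

#' Project a volume at an orientation
#'
#' `image(x, y) = sum over depth of volume(R^T q)` on the rotated grid
#' (trilinear interpolation), then translated by `shift`.  Linear in the
#' volume.
#'
#' @param volume a [density_volume()].
#' @param e an [euler()] triplet.
#' @param shift length-2 pixel shift (default none).
#' @param size output image size (defaults to the volume side; must match).
#' @param wrap_z treat the volume as periodic along the tube (z) axis, so a
#'   simulated tube is effectively infinite; disable for general volumes.
#' @return `n x n` numeric matrix.
#' @export
rotate_project <- function(volume, e, shift = c(0, 0), size = NULL,
                           wrap_z = TRUE) {
  n <- dim(volume$data)[1]
  if (!is.null(size) && size != n)
    stop_tl("requested image size must match the volume box", "tl_invalid_argument")
  check_finite(shift, "shift")
  if (any(abs(shift) >= n)) stop_tl("shift magnitude must be below box size", "tl_invalid_argument")
  R <- rotation_matrix(e)
  cpp_project(as.vector(volume$data), n, R, shift[1], shift[2],
              as.integer(wrap_z))
}

#' Predict the projected pixel position of a 3D point
#'
#' Returns `(R p)_xy / pixel_size + shift`, in pixels relative to the image
#' center; exactly consistent with where [rotate_project()] places an impulse
#' at `p`.
#'
#' @param p length-3 point in Angstrom (volume frame, centered).
#' @param e an [euler()] triplet.
#' @param shift length-2 pixel shift.
#' @param pixel_size Angstrom per pixel.
#' @return length-2 pixel position (x, y) relative to the box center.
#' @export
project_point <- function(p, e, shift = c(0, 0), pixel_size = 1) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_tl("pixel_size must be positive", "tl_invalid_argument")
  R <- rotation_matrix(e)
  q <- R %*% as.numeric(p)
  q[1:2] / pixel_size + shift
}

#' Reconstruct a volume from an image stack by weighted backprojection
#'
#' Each image is smeared back along its viewing direction (the exact adjoint
#' of [rotate_project()], shifts reverted), images optionally phase-flipped
#' by the sign of their CTF first; the accumulated volume is then normalized
#' in Fourier space by a radial ramp that compensates the 1/|f| sampling
#' density of central sections (classic weighted backprojection).
#' Deterministic given its inputs.
#'
#' @param stack an [image_stack()].
#' @param records particle metadata data frame with columns
#'   `rot, tilt, psi, sx, sy` (shifts in pixels) and, for phase flipping,
#'   `defocus` (Angstrom).
#' @param ctf_mode `"none"` or `"phase_flip"`.
#' @param optics an [optics_params()]; required for `ctf_mode = "phase_flip"`.
#' @param weight `"ramp"` (default) or `"none"` (raw adjoint, divided by the
#'   number of images).
#' @param wrap_z smear rays periodically along z (the tube convention);
#'   disable for general volumes.
#' @return a [density_volume()].
#' @export
reconstruct_backproject <- function(stack, records, ctf_mode = c("none", "phase_flip"),
                                    optics = NULL, weight = c("ramp", "none"),
                                    wrap_z = TRUE) {
  ctf_mode <- match.arg(ctf_mode)
  weight <- match.arg(weight)
  m <- n_images(stack)
  if (m == 0) stop_tl("empty stack", "tl_invalid_argument")
  if (nrow(records) != m)
    stop_tl("records and stack must align by index", "tl_invalid_argument")
  if (ctf_mode == "phase_flip") {
    if (is.null(optics) || is.null(records$defocus) || anyNA(records$defocus))
      stop_tl("phase_flip requires optics and per-particle defocus", "tl_invalid_argument")
  }
  n <- dim(stack$data)[1]
  acc <- numeric(n^3)
  for (i in seq_len(m)) {
    img <- get_image(stack, i)
    if (ctf_mode == "phase_flip")
      img <- ctf_phase_flip(img, optics, records$defocus[i])
    R <- rotation_matrix(euler(records$rot[i], records$tilt[i], records$psi[i]))
    cpp_backproject_add(acc, n, img, R, records$sx[i], records$sy[i],
                        as.integer(wrap_z))
  }
  vol <- array(acc / m, dim = rep(n, 3))
  if (weight == "ramp") {
    f <- fft_freq(n, stack$pixel_size)
    fr <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
    w <- pmax(fr, f[2] / 2)            # clip the DC term, keep scale
    vol <- Re(fft(fft(vol) * w, inverse = TRUE)) / n^3
    vol <- vol / stack$pixel_size      # ramp is in 1/A; rescale to per-voxel
  }
  density_volume(vol, stack$pixel_size)
}
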