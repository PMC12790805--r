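#' Sub-particle extraction and reconstruction at model-derived coordinates
#'
#' Localized reconstruction of a small 3D site (here the VD membrane-contact
#' position at the center of a lattice tetramer): the site's projected
#' position is computed per particle from pure geometry, a small box is
#' extracted there, the particle azimuth is advanced by the site's azimuth
#' so every sub-particle places the site on the reference azimuth, and the
#' sub-stack is reconstructed without imposing symmetry.
#'
#' @name subparticle_recon
NULL

#' Lattice contact-site list for sub-particle extraction
#'
#' Nine tube-frame points covering the center of the stacked lattice: the
#' central VD membrane-contact site plus its neighbors one tetramer over in
#' azimuth and one rung over in z (a 3 x 3 patch).  Contact sites sit at
#' every second subunit, so the azimuthal pitch is twice the subunit pitch.
#'
#' @param spec a [tube_lattice_spec()].
#' @param radius radial distance of the sites (default: the VD layer).
#' @return data frame with `x, y, z` (Angstrom), one row per point.
#' @export
lattice_contact_points <- function(spec, radius = spec$layer_radii[["VD"]]) {
  daz <- 2 * 360 / spec$subunits_per_rung
  dz <- spec$rung_spacing_stacked
  grid <- expand.grid(az = c(-daz, 0, daz), z = c(-dz, 0, dz))
  data.frame(x = radius * cos(deg2rad(grid$az)),
             y = radius * sin(deg2rad(grid$az)),
             z = grid$z)
}

#' Compute per-(particle, point) sub-particle offsets and azimuth adjustments
#'
#' The offset is the projected pixel position of the point under the
#' particle's orientation and shift ([project_point()]); the rot adjustment
#' is the point's azimuth about the tube axis, added to the particle's
#' `rot` so the sub-particle frame places the point on the reference
#' azimuth.  Pure geometry; no image access.
#'
#' @param points data frame (or matrix) of tube-frame points, Angstrom,
#'   columns `x, y, z`.
#' @param records particle records.
#' @param pixel_size Angstrom per pixel.
#' @return data frame with one row per (particle, point): `particle`,
#'   `point`, `off_x`, `off_y` (pixels), `rot` (adjusted), `tilt`, `psi`,
#'   `sx`, `sy` (zero: the extraction re-centers exactly), `defocus`.
#' @export
compute_subparticle_offsets <- function(points, records, pixel_size) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points)))
    names(points)[1:3] <- c("x", "y", "z")
  m <- nrow(records); np <- nrow(points)
  az <- rad2deg(atan2(points$y, points$x))
  out <- vector("list", m * np)
  k <- 0
  for (i in seq_len(m)) {
    e <- euler(records$rot[i], records$tilt[i], records$psi[i])
    sh <- c(records$sx[i], records$sy[i])
    for (t in seq_len(np)) {
      k <- k + 1
      off <- project_point(c(points$x[t], points$y[t], points$z[t]), e, sh,
                           pixel_size)
      out[[k]] <- data.frame(
        particle = i, point = t, off_x = off[1], off_y = off[2],
        rot = (records$rot[i] + az[t]) %% 360,
        tilt = records$tilt[i], psi = records$psi[i], sx = 0, sy = 0,
        defocus = if (is.null(records$defocus)) NA_real_ else records$defocus[i])
    }
  }
  do.call(rbind, out)
}

#' Extract sub-particle images at computed offsets
#'
#' Crops a `box`-sized window centered (sub-pixel, via Fourier shift of the
#' parent) at each offset; one sub-image per (particle, point) row.
#'
#' @param stack parent [image_stack()].
#' @param offsets data frame from [compute_subparticle_offsets()].
#' @param box sub-particle box side, pixels (must not exceed the parent box).
#' @param boundary `"error"` (fail when the window leaves the parent) or
#'   `"pad_mean"` (out-of-bounds area filled with the parent mean).
#' @return an [image_stack()] of `nrow(offsets)` sub-images.
#' @export
extract_subparticles <- function(stack, offsets, box,
                                 boundary = c("error", "pad_mean")) {
  boundary <- match.arg(boundary)
  n <- dim(stack$data)[1]
  if (box > n) stop_tl("sub-particle box exceeds the parent box", "tl_invalid_argument")
  half <- box / 2
  out <- array(0, dim = c(box, box, nrow(offsets)))
  c0 <- n / 2 + 1
  sel <- (c0 - half):(c0 + half - 1)
  for (k in seq_len(nrow(offsets))) {
    i <- offsets$particle[k]
    off <- c(offsets$off_x[k], offsets$off_y[k])
    lo <- c0 + off - half; hi <- c0 + off + half - 1
    oob <- any(lo < 1) || any(hi > n)
    if (oob && boundary == "error")
      stop_tl(sprintf("sub-particle window out of bounds for particle %d (point %d)",
                      i, offsets$point[k]), "tl_out_of_bounds")
    img <- get_image(stack, i)
    shifted <- fourier_shift(img, -off)
    win <- shifted[sel, sel]
    if (oob) {
      # replace wrapped-in content with the parent mean
      xs <- sel + round(off[1]); ys <- sel + round(off[2])
      win[xs < 1 | xs > n, ] <- mean(img)
      win[, ys < 1 | ys > n] <- mean(img)
    }
    out[, , k] <- win
  }
  image_stack(out, stack$pixel_size)
}

#' Reconstruct a sub-particle map
#'
#' Backprojects the sub-stack with the adjusted records (no symmetry
#' imposed); optionally polishes orientations first with a local
#' [projection_match()] against a reference.
#'
#' @param substack sub-particle [image_stack()].
#' @param subrecords adjusted records from [compute_subparticle_offsets()].
#' @param polish_ref optional reference [density_volume()] for a local
#'   angular polish.
#' @param polish_stages stages for the polish (see [projection_match()]).
#' @param ... passed to [reconstruct_backproject()].
#' @return a [density_volume()].
#' @export
reconstruct_subparticle <- function(substack, subrecords, polish_ref = NULL,
                                    polish_stages = list(list(search = 4, step = 1,
                                                              reslim = 20, frac = 1)),
                                    ...) {
  if (!is.null(polish_ref)) {
    pm <- projection_match(substack, subrecords, polish_ref, polish_stages)
    subrecords <- pm$records
  }
  reconstruct_backproject(substack, subrecords, ...)
}
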