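#' Region-of-interest signal subtraction (RASTR)
#'
#' The engine that isolates a locally ordered surface patch of a decorated
#' tube: a soft spherical mask placed on the tube surface defines the region
#' of interest (ROI); the projection of the azimuthal-average model with the
#' ROI carved out is scaled and subtracted from each raw particle, leaving
#' ROI signal plus noise; the image is then re-centered on the projected ROI
#' center and re-booked as an independent sub-particle.
#'
#' @name rastr
NULL

#' Build a soft-edged spherical mask in the tube frame
#'
#' @param center_cyl ROI center in tube-frame cylindrical coordinates:
#'   `c(radial distance A, azimuth degrees, z A)`.
#' @param radius sphere radius, Angstrom.
#' @param soft_edge cosine falloff width, Angstrom (0 = hard sphere).
#' @param boxsize box side, voxels.
#' @param pixel_size Angstrom per voxel.
#' @return a [density_volume()] with values in [0, 1]: exactly 1 inside
#'   `radius - soft_edge`, 0 outside `radius`.
#' @export
make_spherical_mask <- function(center_cyl, radius, soft_edge = 20,
                                boxsize = 128, pixel_size = 4) {
  if (radius <= 0 || soft_edge < 0)
    stop_tl("radius must be > 0 and soft_edge >= 0", "tl_invalid_argument")
  r <- center_cyl[1]; az <- deg2rad(center_cyl[2]); z <- center_cyl[3]
  ctr <- c(r * cos(az), r * sin(az), z)
  half <- boxsize / 2 * pixel_size
  if (any(abs(ctr) - radius > half))
    stop_tl("sphere lies entirely outside the box", "tl_invalid_argument")
  cv <- ctr / pixel_size + boxsize / 2
  m <- cpp_sphere_mask(boxsize, cv[1], cv[2], cv[3], radius / pixel_size,
                       soft_edge / pixel_size)
  density_volume(array(m, dim = rep(boxsize, 3)), pixel_size)
}

#' Subtract the projected non-ROI signal from a particle image
#'
#' Projects `azavg * (1 - mask)` at the particle's orientation (CTF-applied
#' when optics and defocus are available), scales it by a per-particle
#' least-squares amplitude fit, and subtracts it; the result retains the ROI
#' signal plus noise.
#'
#' @param image numeric matrix.
#' @param record one-row data frame (or list) with `rot, tilt, psi, sx, sy`
#'   and optionally `defocus`.
#' @param azavg azimuthal-average [density_volume()] on the particle grid.
#' @param mask ROI mask [density_volume()] on the same grid.
#' @param optics an [optics_params()] for CTF modulation (optional).
#' @return the subtracted image matrix.
#' @export
subtract_outside_roi <- function(image, record, azavg, mask, optics = NULL) {
  if (!identical(dim(azavg$data), dim(mask$data)) ||
      abs(azavg$pixel_size - mask$pixel_size) > 1e-9)
    stop_tl("azavg and mask must share the voxel grid", "tl_invalid_argument")
  n <- dim(azavg$data)[1]
  if (any(dim(image) != n)) stop_tl("image and map grids differ", "tl_invalid_argument")
  comp <- azavg$data * (1 - mask$data)
  R <- rotation_matrix(euler(record$rot, record$tilt, record$psi))
  proj <- cpp_project(as.vector(comp), n, R, record$sx, record$sy)
  if (!is.null(optics) && !is.null(record$defocus) && is.finite(record$defocus))
    proj <- apply_ctf(proj, optics, record$defocus)
  den <- sum(proj^2)
  if (den < .Machine$double.eps) return(image)
  image - (sum(image * proj) / den) * proj
}

#' Default ROI center radius for a tube spec
#'
#' Midway between the outer leaflet and the top G layer, so that a
#' 130-185 A ROI covers the full protein depth of one tube surface.
#'
#' @param spec a [tube_lattice_spec()].
#' @return radial distance in Angstrom.
#' @export
roi_center_radius <- function(spec) {
  (spec$leaflet_radii[2] + spec$layer_radii[["topG"]]) / 2
}

#' Create RASTR sub-particles from aligned tube particles
#'
#' For each particle, `n_masks` spherical ROI masks are placed on the tube
#' surface at viewing azimuths drawn per `phi_mode` (`"random"`: uniform on
#' [0, 360); `"edge"`: alternating 90/270, the tube silhouette).  For each
#' mask the non-ROI signal is subtracted, the image is re-centered on the
#' projected mask center (Fourier shift), and a sub-particle record is
#' emitted whose `rot` is the viewing azimuth `(rot + mask azimuth) mod 360`
#' with zero residual shifts.
#'
#' When `fast = TRUE` (default) the subtraction exploits the cylindrical
#' symmetry of the azimuthal average: the complement projection for a mask
#' at volume azimuth `phi_m` under particle azimuth `rot` equals the
#' projection of the mask placed at `beta = rot + phi_m` with `rot = 0`, so
#' in edge mode only two complement volumes are ever built; each is
#' projected once per tilt at `psi = 0` and the per-particle model is
#' obtained by in-plane rotation and translation of that base projection.
#'
#' @param stack an [image_stack()] of raw particles.
#' @param records aligned records (`rot` previously assigned, e.g. by
#'   [azimuthal_average()]'s convention of random azimuths).
#' @param azavg azimuthal-average [density_volume()].
#' @param mask_radius ROI radius, Angstrom (the ROI-size ladder of the
#'   method uses 425, 250, 185, 130).
#' @param n_masks masks per particle.
#' @param phi_mode `"random"` or `"edge"`.
#' @param seed RNG seed for random mask azimuths.
#' @param center_radius radial distance of the ROI center from the tube
#'   axis, Angstrom (see [roi_center_radius()]).
#' @param soft_edge mask falloff, Angstrom.
#' @param optics an [optics_params()] for CTF-matched subtraction (optional).
#' @param fast use the cylindrical-symmetry fast path in edge mode.
#' @return list with `stack` (sub-particles) and `records` (sub-records
#'   with `tl_parent`, `tl_mask_azimuth`, `tl_center_x/y` bookkeeping and
#'   any `tl_` columns of the parents carried over).
#' @export
make_rastr_subparticles <- function(stack, records, azavg, mask_radius,
                                    n_masks = 4, phi_mode = c("random", "edge"),
                                    seed = 1, center_radius, soft_edge = 20,
                                    optics = NULL, fast = TRUE) {
  phi_mode <- match.arg(phi_mode)
  if (n_masks < 1) stop_tl("n_masks must be >= 1", "tl_invalid_argument")
  fast <- fast && phi_mode == "edge"   # random azimuths defeat the cache
  m <- n_images(stack)
  n <- dim(stack$data)[1]
  ps <- stack$pixel_size
  with_seed(seed, {
    beta <- if (phi_mode == "random") {
      matrix(runif(m * n_masks, 0, 360), m, n_masks)
    } else {
      matrix(rep(c(90, 270), length.out = n_masks), m, n_masks, byrow = TRUE)
    }
    base_cache <- list()
    # base projection of the complement volume for mask azimuth b at a given
    # tilt, psi = 0, no shift
    base_for <- function(b, tilt) {
      key <- sprintf("%.6f_%g", b, tilt)
      if (is.null(base_cache[[key]])) {
        msk <- make_spherical_mask(c(center_radius, b, 0), mask_radius,
                                   soft_edge, n, ps)
        comp <- as.vector(azavg$data * (1 - msk$data))
        base_cache[[key]] <<- cpp_project(comp, n,
                                          rotation_matrix(euler(0, tilt, 0)),
                                          0, 0)
      }
      base_cache[[key]]
    }
    out <- array(0, dim = c(n, n, m * n_masks))
    rows <- vector("list", m * n_masks)
    k <- 0
    for (i in seq_len(m)) {
      rec <- records[i, ]
      img <- get_image(stack, i)
      for (j in seq_len(n_masks)) {
        k <- k + 1
        b <- beta[i, j]
        phi_m <- (b - rec$rot) %% 360
        proj <- if (fast) {
          fourier_shift(cpp_rotate_image(base_for(b, rec$tilt), rec$psi),
                        c(rec$sx, rec$sy))
        } else {
          msk <- make_spherical_mask(c(center_radius, phi_m, 0), mask_radius,
                                     soft_edge, n, ps)
          comp <- as.vector(azavg$data * (1 - msk$data))
          R <- rotation_matrix(euler(rec$rot, rec$tilt, rec$psi))
          cpp_project(comp, n, R, rec$sx, rec$sy)
        }
        if (!is.null(optics) && !is.null(rec$defocus) && is.finite(rec$defocus))
          proj <- apply_ctf(proj, optics, rec$defocus)
        den <- sum(proj^2)
        res <- if (den > .Machine$double.eps)
          img - (sum(img * proj) / den) * proj else img
        p_m <- center_radius * c(cos(deg2rad(phi_m)), sin(deg2rad(phi_m)), 0)
        ctr <- project_point(p_m, euler(rec$rot, rec$tilt, rec$psi),
                             c(rec$sx, rec$sy), ps)
        out[, , k] <- fourier_shift(res, -ctr)
        row <- data.frame(rot = b %% 360, tilt = rec$tilt, psi = rec$psi,
                          sx = 0, sy = 0,
                          defocus = if (is.null(rec$defocus)) NA_real_ else rec$defocus,
                          tl_parent = i, tl_mask_azimuth = phi_m,
                          tl_center_x = ctr[1], tl_center_y = ctr[2])
        for (nm in grep("^tl_", names(records), value = TRUE))
          if (is.null(row[[nm]])) row[[nm]] <- rec[[nm]]
        rows[[k]] <- row
      }
    }
    list(stack = image_stack(out, ps), records = do.call(rbind, rows))
  })
}
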