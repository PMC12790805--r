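#' Generative parameters of a decorated nanotube
#'
#' Describes a GalCer-like lipid nanotube (two concentric leaflet shells)
#' decorated by a locally ordered protein lattice built from rungs of
#' subunits.  Radial layers, from the membrane outward, are the variable
#' domain (VD), the stalk, the bottom G domain and -- in the stacked state
#' only -- the top G domain.  Distances in Angstrom, angles in degrees.
#'
#' Defaults are desk-scale: a 20 nm inner lumen (inner leaflet radius 100 A)
#' with a 40 A bilayer, protein layers at VD 150, stalk 180, bottom G 210,
#' top G 235 A, twelve subunits per rung, right-handed inter-rung twist of
#' +12 degrees, rung spacing 50 A (stacked) / 70 A (relaxed).  The layer
#' radii are free simulator parameters chosen to preserve the ordering and
#' approximate spacing of the real layers while fitting, with three blob
#' widths to spare, inside the default 128-voxel, 4 A/voxel box.
#'
#' @param lumen_diameter inner lumen diameter, A.
#' @param leaflet_radii radii of the inner/outer membrane leaflet shells, A.
#' @param layer_radii named radii of the protein layers
#'   (`VD`, `stalk`, `bottomG`, `topG`), strictly increasing beyond the
#'   outer leaflet.
#' @param rung_rise base axial rise per rung for strict-helix construction, A.
#' @param twist_per_subunit inter-rung azimuthal twist, degrees; positive =
#'   right-handed.
#' @param subunits_per_rung subunits per circumferential rung.
#' @param rung_spacing_stacked,rung_spacing_relaxed state-dependent rung
#'   spacing, A (`relaxed >= stacked`).
#' @param spacing_jitter_sd rung-level spacing jitter, A (see
#'   [build_lattice_volume()]).
#' @param azimuthal_walk_sd per-subunit step of the azimuthal height walk,
#'   A: sets how fast lattice register decoheres around the circumference
#'   (local order only; a large ROI spanning many subunits sees mutually
#'   dephased columns).
#' @param stacked_fraction fraction of particles in the stacked state.
#' @param blob_sd Gaussian width of the pseudo-domain densities, A.
#' @param blob_amplitude peak amplitude of the protein blobs relative to the
#'   membrane shells; the published edge-view class averages show protein
#'   features at least as strong as the membrane, which requires a ratio
#'   well above 1 (contact rods get 0.7x this value).
#' @param contact_on add a VD-membrane contact rod (stacked state only).
#' @param membrane_sd Gaussian cross-section of the leaflet shells, A.
#' @return object of class `tube_lattice_spec`.
#' @export
tube_lattice_spec <- function(lumen_diameter = 200,
                              leaflet_radii = c(lumen_diameter / 2, lumen_diameter / 2 + 40),
                              layer_radii = c(VD = 150, stalk = 180, bottomG = 210, topG = 235),
                              rung_rise = 50,
                              twist_per_subunit = 12,
                              subunits_per_rung = 12,
                              rung_spacing_stacked = 50,
                              rung_spacing_relaxed = 70,
                              spacing_jitter_sd = 5,
                              azimuthal_walk_sd = 10,
                              stacked_fraction = 0.5,
                              blob_sd = 7,
                              blob_amplitude = 2.5,
                              contact_on = TRUE,
                              membrane_sd = 10) {
  spec <- list(lumen_diameter = lumen_diameter, leaflet_radii = leaflet_radii,
               layer_radii = layer_radii, rung_rise = rung_rise,
               twist_per_subunit = twist_per_subunit,
               subunits_per_rung = as.integer(subunits_per_rung),
               rung_spacing_stacked = rung_spacing_stacked,
               rung_spacing_relaxed = rung_spacing_relaxed,
               spacing_jitter_sd = spacing_jitter_sd,
               azimuthal_walk_sd = azimuthal_walk_sd,
               stacked_fraction = stacked_fraction, blob_sd = blob_sd,
               blob_amplitude = blob_amplitude,
               contact_on = isTRUE(contact_on), membrane_sd = membrane_sd)
  if (lumen_diameter <= 0) stop_tl("lumen_diameter must be > 0", "tl_invalid_argument")
  if (blob_amplitude <= 0) stop_tl("blob_amplitude must be > 0", "tl_invalid_argument")
  radii <- c(leaflet_radii, layer_radii[c("VD", "stalk", "bottomG", "topG")])
  if (anyNA(radii) || any(diff(radii) <= 0))
    stop_tl("radii must be strictly ordered: leaflets < VD < stalk < bottomG < topG",
            "tl_invalid_argument")
  if (rung_spacing_relaxed < rung_spacing_stacked)
    stop_tl("rung_spacing_relaxed must be >= rung_spacing_stacked", "tl_invalid_argument")
  if (stacked_fraction < 0 || stacked_fraction > 1)
    stop_tl("stacked_fraction must lie in [0, 1]", "tl_invalid_argument")
  if (azimuthal_walk_sd < 0) stop_tl("azimuthal_walk_sd must be >= 0", "tl_invalid_argument")
  if (spacing_jitter_sd < 0 || blob_sd <= 0 || rung_rise <= 0)
    stop_tl("blob_sd and rung_rise must be positive, jitter non-negative",
            "tl_invalid_argument")
  structure(spec, class = "tube_lattice_spec")
}

#' @export
print.tube_lattice_spec <- function(x, ...) {
  cat(sprintf("tube_lattice_spec: lumen %.0f A, leaflets %.0f/%.0f A, topG %.0f A\n",
              x$lumen_diameter, x$leaflet_radii[1], x$leaflet_radii[2],
              x$layer_radii[["topG"]]))
  cat(sprintf("  rungs: %d subunits, twist %+.1f deg, spacing %.0f/%.0f A (stacked/relaxed), jitter sd %.1f A\n",
              x$subunits_per_rung, x$twist_per_subunit,
              x$rung_spacing_stacked, x$rung_spacing_relaxed, x$spacing_jitter_sd))
  invisible(x)
}

#' Microscope optics parameters
#'
#' @param pixel_size Angstrom per pixel.
#' @param voltage acceleration voltage, kV.
#' @param spherical_aberration Cs, mm.
#' @param amplitude_contrast fraction in [0, 1].
#' @param defocus_range (min, max) underfocus, Angstrom.
#' @return object of class `optics_params`.
#' @export
optics_params <- function(pixel_size = 4, voltage = 300,
                          spherical_aberration = 2.7,
                          amplitude_contrast = 0.07,
                          defocus_range = c(5000, 20000)) {
  if (pixel_size <= 0) stop_tl("pixel_size must be > 0", "tl_invalid_argument")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop_tl("amplitude_contrast must lie in [0, 1]", "tl_invalid_argument")
  if (diff(defocus_range) < 0) stop_tl("defocus min must be <= max", "tl_invalid_argument")
  structure(list(pixel_size = pixel_size, voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 defocus_range = defocus_range),
            class = "optics_params")
}

#' Relativistic electron wavelength in Angstrom
#' @param voltage_kv acceleration voltage in kV.
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF at given spatial frequencies
#'
#' Scalar/vector version of [ctf_2d()]: same formula, arbitrary
#' frequencies.
#'
#' @param f spatial frequency, 1/Angstrom.
#' @param optics an [optics_params()].
#' @param defocus underfocus, Angstrom.
#' @return CTF values.
#' @export
ctf_1d <- function(f, optics, defocus) {
  lambda <- electron_wavelength(optics$voltage)
  cs <- optics$spherical_aberration * 1e7
  chi <- pi * lambda * defocus * f^2 - (pi / 2) * cs * lambda^3 * f^4
  a <- optics$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

#' Evaluate the CTF on the FFT grid of an n x n image
#'
#' `CTF(f) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with
#' `chi = pi lambda dz f^2 - (pi/2) Cs lambda^3 f^4` (positive `dz` =
#' underfocus), so `CTF(0) = -A`.
#'
#' @param n image side, pixels.
#' @param optics an [optics_params()].
#' @param defocus underfocus, Angstrom.
#' @return n x n matrix of CTF values in FFT layout.
#' @export
ctf_2d <- function(n, optics, defocus) {
  f2 <- freq_grid2d(n, optics$pixel_size)^2
  lambda <- electron_wavelength(optics$voltage)
  cs <- optics$spherical_aberration * 1e7    # mm -> A
  chi <- pi * lambda * defocus * f2 - (pi / 2) * cs * lambda^3 * f2^2
  a <- optics$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

#' Apply (or phase-flip by) the contrast transfer function
#'
#' `apply_ctf` multiplies the image spectrum by the CTF; `ctf_phase_flip`
#' multiplies by its sign, restoring feature polarity without amplitude
#' correction.
#'
#' @param image numeric matrix.
#' @param optics an [optics_params()].
#' @param defocus underfocus, Angstrom.
#' @return real image matrix.
#' @export
apply_ctf <- function(image, optics, defocus) {
  h <- ctf_2d(nrow(image), optics, defocus)
  Re(fft(fft(image) * h, inverse = TRUE)) / length(image)
}

#' @rdname apply_ctf
#' @export
ctf_phase_flip <- function(image, optics, defocus) {
  h <- sign(ctf_2d(nrow(image), optics, defocus))
  Re(fft(fft(image) * h, inverse = TRUE)) / length(image)
}

#' @rdname apply_ctf
#' @param wiener Wiener constant (inverse SNR) regularizing the CTF
#'   inversion.
#' @export
ctf_wiener <- function(image, optics, defocus, wiener = 0.2) {
  h <- ctf_2d(nrow(image), optics, defocus)
  w <- h / (h^2 + wiener)
  Re(fft(fft(image) * w, inverse = TRUE)) / length(image)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(code)
}

# Gaussian blob (separable) accumulated in place into a flat n^3 buffer.
add_blob <- function(buf, n, center, sigma, amplitude, pixel_size) {
  cv <- center / pixel_size + n / 2   # 0-based voxel center
  cpp_add_blob(buf, n, cv[1], cv[2], cv[3], sigma / pixel_size, amplitude)
  invisible(buf)
}

#' Build a decorated-nanotube density volume
#'
#' The volume is the sum of two concentric cylindrical Gaussian shells (the
#' membrane leaflets) and Gaussian blobs at the lattice sites: per subunit a
#' stalk and a bottom-G blob; in the stacked state additionally a top-G blob
#' and, if `contact_on`, a VD-membrane contact rod at every second subunit
#' (the tetramer centers).
#'
#' Local (not global) order: rung `k` sits at `z = k * spacing + e_k` with
#' `e_k ~ N(0, spacing_jitter_sd)`, and every subunit column `j` carries an
#' additional axial offset `w_j` from a Brownian-bridge random walk around
#' the circumference with per-subunit step sd `azimuthal_walk_sd`.  Nearby
#' columns therefore stay in register while columns far apart in azimuth
#' dephase, which is what confines useful signal to a small region of
#' interest.  `state = "mixed"` builds stacked rungs for z < 0 and relaxed
#' rungs for z >= 0.
#'
#' @param spec a [tube_lattice_spec()].
#' @param state `"stacked"`, `"relaxed"` or `"mixed"`.
#' @param boxsize box side in voxels (even).
#' @param pixel_size Angstrom per voxel.
#' @param seed RNG seed for the disorder draws (`NULL` = current RNG state).
#' @param decorated set `FALSE` for a bare membrane tube (no protein).
#' @return list with `volume` (a [density_volume()]) and `sites` (data frame
#'   of lattice sites: `x, y, z` in Angstrom, `rung`, `subunit`, `state`).
#' @export
build_lattice_volume <- function(spec, state = c("stacked", "relaxed", "mixed"),
                                 boxsize = 128, pixel_size = 4, seed = NULL,
                                 decorated = TRUE) {
  state <- match.arg(state)
  half <- boxsize / 2 * pixel_size
  if (decorated && half < spec$layer_radii[["topG"]] + 3 * spec$blob_sd)
    stop_tl("box too small: must contain the top G radius plus 3 blob widths",
            "tl_invalid_argument")
  n <- boxsize
  ax <- (seq_len(n) - (n / 2 + 1)) * pixel_size
  r_xy <- sqrt(outer(ax^2, ax^2, "+"))
  shell2d <- exp(-(r_xy - spec$leaflet_radii[1])^2 / (2 * spec$membrane_sd^2)) +
    exp(-(r_xy - spec$leaflet_radii[2])^2 / (2 * spec$membrane_sd^2))
  buf <- as.numeric(rep(shell2d, n))
  sites <- NULL
  if (decorated) {
    with_seed(seed, {
      S <- spec$subunits_per_rung
      # shared azimuthal height field (Brownian bridge, zero mean)
      steps <- rnorm(S, 0, spec$azimuthal_walk_sd)
      w <- cumsum(steps) - (seq_len(S) / S) * sum(steps)
      w <- w - mean(w)
      spacing <- c(stacked = spec$rung_spacing_stacked, relaxed = spec$rung_spacing_relaxed)
      kmax <- ceiling((half + spacing[["relaxed"]]) / spacing[["stacked"]])
      ks <- -kmax:kmax
      # inter-rung spacings are independently perturbed, so the axial
      # register follows a random walk away from the center rung: order is
      # local along z as well as around the circumference
      incr <- rnorm(2 * kmax, 0, spec$spacing_jitter_sd)
      zoff <- c(rev(cumsum(incr[seq_len(kmax)])) * -1, 0,
                cumsum(incr[kmax + seq_len(kmax)]))
      rows <- list()
      for (ki in seq_along(ks)) {
        k <- ks[ki]
        sp <- if (state == "mixed") {
          if (k < 0) spacing[["stacked"]] else spacing[["relaxed"]]
        } else spacing[[state]]
        zk <- k * sp + zoff[ki]
        if (abs(zk) > half + 3 * spec$blob_sd) next
        st <- if (state == "mixed") (if (zk < 0) "stacked" else "relaxed") else state
        for (j in seq_len(S)) {
          a <- deg2rad((j - 1) * 360 / S + k * spec$twist_per_subunit)
          z <- zk + w[j]
          ca <- cos(a); sa <- sin(a)
          lr <- spec$layer_radii
          amp <- spec$blob_amplitude
          add_blob(buf, n, c(lr[["stalk"]] * ca, lr[["stalk"]] * sa, z),
                   spec$blob_sd, amp, pixel_size)
          add_blob(buf, n, c(lr[["bottomG"]] * ca, lr[["bottomG"]] * sa, z),
                   spec$blob_sd, amp, pixel_size)
          if (st == "stacked") {
            add_blob(buf, n, c(lr[["topG"]] * ca, lr[["topG"]] * sa, z),
                     spec$blob_sd, amp, pixel_size)
            if (spec$contact_on && j %% 2 == 1) {
              for (rr in seq(spec$leaflet_radii[2], lr[["VD"]], length.out = 3))
                add_blob(buf, n, c(rr * ca, rr * sa, z),
                         spec$blob_sd * 0.6, 0.7 * amp, pixel_size)
            }
          }
          rows[[length(rows) + 1]] <-
            data.frame(x = lr[["stalk"]] * ca, y = lr[["stalk"]] * sa, z = z,
                       rung = k, subunit = j, state = st)
        }
      }
      sites <- do.call(rbind, rows)
    })
  }
  list(volume = density_volume(array(buf, dim = c(n, n, n)), pixel_size),
       sites = sites)
}

#' Simulate boxed tubule particle images with CTF and noise
#'
#' For each particle: draw the lattice state by `stacked_fraction`, draw
#' `rot` per `phi_mode` (uniform 0-360 or edge 90/270), `tilt` from
#' \{90, 270\} equiprobably, `psi` uniform on [0, 360); draw shifts uniform
#' in the across-tube (+/- 5 px) and along-tube (+/- 8 px) directions;
#' project the state volume, apply the CTF at a defocus drawn uniformly from
#' the optics range, and add i.i.d. Gaussian noise.  Fully reproducible from
#' `seed`.
#'
#' If `snr` is given instead of `noise_sd`, the noise sd is set so that the
#' mean signal variance over the tube-occupied region (pixels within the top
#' G radius plus 3 blob widths of the tube axis) divided by the noise
#' variance equals `snr`.
#'
#' @param spec a [tube_lattice_spec()].
#' @param optics an [optics_params()].
#' @param n number of particles.
#' @param noise_sd additive Gaussian noise sd (0 = noise-free).
#' @param snr alternative noise specification (signal variance over the tube
#'   region / noise variance); overrides `noise_sd`.
#' @param phi_mode `"random"` or `"edge"`.
#' @param seed RNG seed.
#' @param boxsize box side, pixels.
#' @param decorated set `FALSE` for bare membrane tubes.
#' @return list with `stack` (an [image_stack()]), `records` (ground-truth
#'   particle metadata: `rot, tilt, psi, sx, sy, defocus` plus `tl_state`,
#'   `tl_diameter`, `tl_seed`), `noise_sd`, and the state volumes.
#' @export
simulate_particles <- function(spec, optics, n, noise_sd = 0, snr = NULL,
                               phi_mode = c("random", "edge"), seed = 1,
                               boxsize = 128, decorated = TRUE) {
  phi_mode <- match.arg(phi_mode)
  if (n < 1) stop_tl("n must be >= 1", "tl_invalid_argument")
  ps <- optics$pixel_size
  with_seed(seed, {
    vols <- list(
      stacked = build_lattice_volume(spec, "stacked", boxsize, ps, decorated = decorated),
      relaxed = build_lattice_volume(spec, "relaxed", boxsize, ps, decorated = decorated))
    states <- ifelse(runif(n) < spec$stacked_fraction, "stacked", "relaxed")
    rot <- if (phi_mode == "random") runif(n, 0, 360) else sample(c(90, 270), n, replace = TRUE)
    tilt <- sample(c(90, 270), n, replace = TRUE)
    psi <- runif(n, 0, 360)
    s_perp <- runif(n, -5, 5)
    s_par <- runif(n, -8, 8)
    defocus <- runif(n, optics$defocus_range[1], optics$defocus_range[2])
    dat <- array(0, dim = c(boxsize, boxsize, n))
    sx <- sy <- numeric(n)
    region_var <- numeric(n)
    r_max <- spec$layer_radii[["topG"]] + 3 * spec$blob_sd
    ax <- (seq_len(boxsize) - (boxsize / 2 + 1))
    for (i in seq_len(n)) {
      e <- euler(rot[i], tilt[i], psi[i])
      R <- rotation_matrix(e)
      u_par <- R[1:2, 3]                       # image direction of the tube axis
      u_par <- u_par / sqrt(sum(u_par^2))
      u_perp <- c(-u_par[2], u_par[1])
      s <- s_perp[i] * u_perp + s_par[i] * u_par
      sx[i] <- s[1]; sy[i] <- s[2]
      img <- rotate_project(vols[[states[i]]]$volume, e, s)
      img <- apply_ctf(img, optics, defocus[i])
      dat[, , i] <- img
      # tube-occupied region: within r_max of the projected axis line
      dperp <- abs(outer(ax - s[1], ax - s[2], function(a, b) a * u_perp[1] + b * u_perp[2]))
      region_var[i] <- var(img[dperp * ps <= r_max])
    }
    if (!is.null(snr)) noise_sd <- sqrt(mean(region_var) / snr)
    if (noise_sd > 0)
      dat <- dat + array(rnorm(length(dat), 0, noise_sd), dim = dim(dat))
    records <- data.frame(rot = rot, tilt = tilt, psi = psi, sx = sx, sy = sy,
                          defocus = defocus,
                          tl_state = states,
                          tl_diameter = 2 * spec$leaflet_radii[2],
                          tl_seed = seed)
    list(stack = image_stack(dat, ps), records = records, noise_sd = noise_sd,
         volumes = vols)
  })
}
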