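test_that("lattice volumes have the designed radial structure", {
  spec <- tl_spec()
  b <- build_lattice_volume(spec, "stacked", 96, 6, seed = 2)
  prof <- radial_profile(b$volume)
  # leaflet shells peak at their radii within one voxel
  pk <- prof$radius[order(-prof$density)[1:4]]
  expect_true(any(abs(pk - spec$leaflet_radii[1]) <= 6))
  expect_true(any(abs(pk - spec$leaflet_radii[2]) <= 6))

  # relaxed state: no density in the top-G radial band
  br <- build_lattice_volume(spec, "relaxed", 96, 6, seed = 2)
  profr <- radial_profile(br$volume)
  band <- function(p, lo, hi) mean(p$density[p$radius >= lo & p$radius <= hi])
  top_r <- band(profr, spec$layer_radii[["topG"]] - 7, spec$layer_radii[["topG"]] + 7)
  stalk_r <- band(profr, spec$layer_radii[["stalk"]] - 7, spec$layer_radii[["stalk"]] + 7)
  expect_lt(top_r, 0.1 * stalk_r)
  # stacked state: top-G band populated, and contact density bridges
  # the outer leaflet to the VD band
  profs <- radial_profile(b$volume)
  top_s <- band(profs, spec$layer_radii[["topG"]] - 7, spec$layer_radii[["topG"]] + 7)
  expect_gt(top_s, 0.3 * band(profs, spec$layer_radii[["stalk"]] - 7,
                              spec$layer_radii[["stalk"]] + 7))
  # contact rods add density between the outer leaflet and the VD layer;
  # the contact_on = FALSE twin of the same volume is the exact control
  b_nc <- build_lattice_volume(tl_spec(contact_on = FALSE), "stacked", 96, 6,
                               seed = 2)
  prof_nc <- radial_profile(b_nc$volume)
  bridge_s <- band(profs, spec$leaflet_radii[2] + 4, spec$layer_radii[["VD"]] + 4)
  bridge_nc <- band(prof_nc, spec$leaflet_radii[2] + 4, spec$layer_radii[["VD"]] + 4)
  bridge_r <- band(profr, spec$leaflet_radii[2] + 4, spec$layer_radii[["VD"]] + 4)
  # the sparse rods raise the ring mean a few percent above the membrane
  # tail; the relaxed state matches the no-contact control exactly
  expect_gt(bridge_s - bridge_nc, 0.03 * bridge_nc)
  expect_lt(abs(bridge_r - bridge_nc) / bridge_nc, 0.01)

  expect_error(build_lattice_volume(spec, "stacked", 64, 4),
               class = "tl_invalid_argument")
  expect_error(tube_lattice_spec(rung_spacing_relaxed = 30),
               class = "tl_invalid_argument")
  expect_error(tube_lattice_spec(stacked_fraction = 1.2),
               class = "tl_invalid_argument")
})

test_that("axial periodicity decays monotonically with spacing jitter", {
  spec0 <- tl_spec()
  peaks <- sapply(c(0, 4, 9), function(j) {
    spec <- tl_spec(spacing_jitter_sd = j)
    b <- build_lattice_volume(spec, "stacked", 96, 6, seed = 3)
    v <- b$volume$data
    ring <- {
      ax <- (1:96 - 49) * 6
      r <- sqrt(outer(ax^2, ax^2, "+"))
      r >= 170 & r <= 245
    }
    zprof <- vapply(1:96, function(iz) mean(v[, , iz][ring]), numeric(1))
    zprof <- zprof - mean(zprof)
    # spectral amplitude at the exact rung frequency (grid-alias free)
    z <- (1:96 - 49) * 6
    f0 <- 1 / spec$rung_spacing_stacked
    Mod(sum(zprof * exp(-2i * pi * f0 * z))) / sqrt(sum(zprof^2))
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("CTF follows the closed-form zero locations and composition", {
  opt0 <- tl_optics()
  expect_equal(ctf_2d(32, opt0, 12000)[1, 1], -opt0$amplitude_contrast,
               tolerance = 1e-12)
  # near-zero amplitude contrast so the first zero sits at the closed form
  opt <- tl_optics(pixel_size = 2, spherical_aberration = 0,
                   amplitude_contrast = 0.02)
  n <- 256
  h <- ctf_2d(n, opt, defocus = 15000)
  # first zero of the pure-defocus CTF (small amplitude contrast shifts it
  # slightly; locate the first sign change along the frequency axis)
  lambda <- electron_wavelength(opt$voltage)
  f0 <- sqrt(1 / (lambda * 15000))
  fx <- tubelattice:::fft_freq(n, opt$pixel_size)
  hrow <- h[, 1]
  pos <- which(hrow[1:(n / 2)] < 0 & c(hrow[2:(n / 2)], NA) >= 0)[1]
  # interpolate the crossing; amplitude contrast makes the predicted zero
  # sit at sin(chi) = -A/sqrt(1-A^2) ~ shifts < 1%
  fcross <- fx[pos] + (fx[pos + 1] - fx[pos]) *
    (0 - hrow[pos]) / (hrow[pos + 1] - hrow[pos])
  expect_lt(abs(fcross - f0) / f0, 0.01)

  # applying the CTF twice multiplies the spectrum by CTF^2
  set.seed(9)
  img <- matrix(rnorm(64^2), 64, 64)
  opt2 <- tl_optics(pixel_size = 4)
  once <- apply_ctf(img, opt2, 12000)
  twice <- apply_ctf(once, opt2, 12000)
  h2 <- ctf_2d(64, opt2, 12000)
  direct <- Re(fft(fft(img) * h2^2, inverse = TRUE)) / 64^2
  expect_equal(twice, direct, tolerance = 1e-6)
})

test_that("particle simulation is reproducible and honors its contracts", {
  spec <- tl_spec()
  opt <- tl_optics()
  a <- simulate_particles(spec, opt, 4, noise_sd = 0.5, seed = 42, boxsize = 64,
                          decorated = FALSE)
  b <- simulate_particles(spec, opt, 4, noise_sd = 0.5, seed = 42, boxsize = 64,
                          decorated = FALSE)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$records, b$records)

  # noise-free images equal their CTF-modulated projections exactly
  nf <- simulate_particles(spec, opt, 2, noise_sd = 0, seed = 7, boxsize = 64,
                           decorated = FALSE)
  r <- nf$records[1, ]
  vol <- build_lattice_volume(spec, "stacked", 64, opt$pixel_size,
                              decorated = FALSE)$volume
  img <- apply_ctf(rotate_project(vol, euler(r$rot, r$tilt, r$psi),
                                  c(r$sx, r$sy)), opt, r$defocus)
  expect_equal(get_image(nf$stack, 1), img, tolerance = 1e-10)

  # empirical state frequency follows the binomial at n = 2000
  spec6 <- tl_spec(stacked_fraction = 0.6)
  big <- simulate_particles(spec6, opt, 2000, noise_sd = 0, seed = 1234,
                            boxsize = 32, decorated = FALSE)
  frac <- mean(big$records$tl_state == "stacked")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))

  # mean image intensity is invariant to phi_mode
  # box large enough that the tube is never clipped, so the projected DC
  # cannot depend on the drawn orientations
  e1 <- simulate_particles(spec, opt, 12, noise_sd = 0, seed = 5, boxsize = 96,
                           decorated = FALSE, phi_mode = "random")
  e2 <- simulate_particles(spec, opt, 12, noise_sd = 0, seed = 5, boxsize = 96,
                           decorated = FALSE, phi_mode = "edge")
  expect_lt(abs(mean(e1$stack$data) - mean(e2$stack$data)),
            0.02 * sd(e1$stack$data))
})
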