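test_that("spherical masks obey their geometric contract", {
  # hard 130 A ball: volume within 2% of (4/3) pi r^3
  m <- make_spherical_mask(c(0, 0, 0), 130, soft_edge = 0, boxsize = 80,
                           pixel_size = 4)
  vol_vox <- sum(m$data) * 4^3
  expect_lt(abs(vol_vox - 4 / 3 * pi * 130^3) / (4 / 3 * pi * 130^3), 0.02)
  expect_equal(m$data[41, 41, 41], 1)
  expect_equal(max(m$data[abs((1:80) - 41) * 4 > 135, , ]), 0)

  # soft mask: exactly 1 inside radius - soft_edge, 0 outside radius
  ms <- make_spherical_mask(c(100, 45, 20), 90, soft_edge = 20, boxsize = 64,
                            pixel_size = 5)
  expect_true(all(ms$data >= 0 & ms$data <= 1))
  ctr <- c(100 * cos(pi / 4), 100 * sin(pi / 4), 20) / 5 + 33
  expect_equal(ms$data[round(ctr[1]), round(ctr[2]), round(ctr[3])], 1)

  # two masks at opposite azimuths are related by a 180-degree z-rotation
  m1 <- make_spherical_mask(c(120, 0, 0), 80, 15, 48, 5)
  m2 <- make_spherical_mask(c(120, 180, 0), 80, 15, 48, 5)
  r180 <- tubelattice:::cpp_affine_volume(as.vector(m2$data), 48,
                                          rotation_matrix(euler(180, 0, 0)),
                                          c(0, 0, 0))
  # compare away from the boundary where interpolation differs
  expect_lt(mean(abs(array(r180, dim = rep(48, 3)) - m1$data)), 0.005)

  expect_error(make_spherical_mask(c(5000, 0, 0), 50, 10, 48, 4),
               class = "tl_invalid_argument")
})

test_that("subtraction is exact within the span of the azimuthal model", {
  spec <- tl_spec()
  n <- 96; ps <- 4
  azavg <- build_lattice_volume(spec, "stacked", n, ps, decorated = FALSE)$volume
  zero_mask <- density_volume(array(0, dim = rep(n, 3)), ps)
  full_mask <- density_volume(array(1, dim = rep(n, 3)), ps)
  set.seed(41)
  for (i in 1:10) {
    rec <- list(rot = runif(1, 0, 360), tilt = sample(c(90, 270), 1),
                psi = runif(1, 0, 360), sx = runif(1, -4, 4),
                sy = runif(1, -4, 4), defocus = NA_real_)
    img <- rotate_project(azavg, euler(rec$rot, rec$tilt, rec$psi),
                          c(rec$sx, rec$sy))
    res <- subtract_outside_roi(img, rec, azavg, zero_mask)
    expect_lt(sd(res) / sd(img), 1e-6)
    # mask covering the whole box: nothing subtracted
    res2 <- subtract_outside_roi(img, rec, azavg, full_mask)
    expect_identical(res2, img)
  }
})

test_that("subtraction isolates an in-ROI perturbation", {
  spec <- tl_spec()
  n <- 128; ps <- 4
  azavg <- build_lattice_volume(spec, "stacked", n, ps, decorated = FALSE)$volume
  # ROI over the featureless region beyond the membrane, bump wholly inside
  mask <- make_spherical_mask(c(210, 30, 0), 50, soft_edge = 15,
                              boxsize = n, pixel_size = ps)
  buf <- as.numeric(array(0, dim = rep(n, 3)))
  ctr <- c(210 * cos(pi / 6), 210 * sin(pi / 6), 0)
  tubelattice:::add_blob(buf, n, ctr, 10, 1, ps)
  bump <- array(buf, dim = rep(n, 3))
  volplus <- density_volume(azavg$data + bump, ps)
  rec <- list(rot = 0, tilt = 90, psi = 25, sx = 1, sy = -2, defocus = NA_real_)
  e <- euler(rec$rot, rec$tilt, rec$psi)
  img <- rotate_project(volplus, e, c(rec$sx, rec$sy))
  res <- subtract_outside_roi(img, rec, azavg, mask)
  bump_proj <- rotate_project(density_volume(bump, ps), e, c(rec$sx, rec$sy))
  expect_gt(ncc(res, bump_proj), 0.95)
})

test_that("RASTR sub-particles carry correct bookkeeping", {
  spec <- tl_spec()
  opt <- tl_optics()
  sim <- simulate_particles(spec, opt, 10, noise_sd = 0, seed = 43)
  recs <- align_tube_stack(sim$stack, sim$records)
  recs <- assign_random_orientations(recs, seed = 2)
  azavg <- azimuthal_average(sim$stack, recs, assign = FALSE,
                             ctf_mode = "phase_flip", optics = opt)
  sub <- make_rastr_subparticles(sim$stack, recs, azavg, 185, n_masks = 4,
                                 phi_mode = "random", seed = 3,
                                 center_radius = roi_center_radius(spec),
                                 optics = opt, fast = FALSE)
  expect_equal(n_images(sub$stack), 40)
  expect_equal(nrow(sub$records), 40)
  expect_true(all(abs((sub$records$tl_mask_azimuth + recs$rot[sub$records$tl_parent]) %% 360 -
                        sub$records$rot) %% 360 < 1e-6))
  # edge mode: every sub-record azimuth is 90 or 270
  sub_e <- make_rastr_subparticles(sim$stack, recs, azavg, 185, n_masks = 2,
                                   phi_mode = "edge", seed = 3,
                                   center_radius = roi_center_radius(spec),
                                   optics = opt)
  expect_true(all(sub_e$records$rot %in% c(90, 270)))
  expect_error(make_rastr_subparticles(sim$stack, recs, azavg, 185,
                                       n_masks = 0, phi_mode = "edge",
                                       center_radius = 187.5),
               class = "tl_invalid_argument")
  # fast path agrees with the generic path on edge masks: the sub-particle
  # content matches closely, with worst-case differences limited to the
  # interpolation of the in-plane decomposition
  sub_g <- make_rastr_subparticles(sim$stack, recs, azavg, 185, n_masks = 2,
                                   phi_mode = "edge", seed = 3,
                                   center_radius = roi_center_radius(spec),
                                   optics = opt, fast = FALSE)
  agree <- sapply(1:n_images(sub_e$stack), function(i)
    ncc(get_image(sub_e$stack, i), get_image(sub_g$stack, i)))
  expect_gt(median(agree), 0.85)
  expect_gt(min(agree), 0.6)
})

test_that("edge sub-particles match the masked ground-truth projection", {
  spec <- tl_spec()
  opt <- tl_optics()
  sim <- simulate_particles(spec, opt, 20, noise_sd = 0, seed = 47)
  recs <- align_tube_stack(sim$stack, sim$records)
  # use the true azimuth so we can compare against the true masked volume
  recs$rot <- sim$records$rot
  recs$tilt <- sim$records$tilt
  azavg <- azimuthal_average(sim$stack, recs, assign = FALSE,
                             ctf_mode = "phase_flip", optics = opt)
  i <- 1
  sub <- make_rastr_subparticles(
    image_stack(sim$stack$data[, , i, drop = FALSE], 4), recs[i, ], azavg,
    mask_radius = 185, n_masks = 1, phi_mode = "edge", seed = 5,
    center_radius = roi_center_radius(spec), optics = opt)
  # ground truth: same mask applied to the true state volume, projected with
  # the true orientation and CTF, re-centered identically
  phi_m <- sub$records$tl_mask_azimuth[1]
  msk <- make_spherical_mask(c(roi_center_radius(spec), phi_m, 0), 185, 20,
                             128, 4)
  state <- sim$records$tl_state[i]
  volroi <- density_volume(sim$volumes[[state]]$volume$data * msk$data, 4)
  tr <- sim$records[i, ]
  e <- euler(tr$rot, tr$tilt, tr$psi)
  proj <- apply_ctf(rotate_project(volroi, e, c(tr$sx, tr$sy)), opt, tr$defocus)
  ctr <- c(sub$records$tl_center_x[1], sub$records$tl_center_y[1])
  truth <- fourier_shift(proj, -ctr)
  got <- get_image(sub$stack, 1)
  # compare within the ROI core (the soft rim blends ROI signal with the
  # residual of the subtracted average)
  roi <- abs(((1:128) - 65) * 4) <= 80
  expect_gt(ncc(got[roi, roi], truth[roi, roi]), 0.9)
})
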