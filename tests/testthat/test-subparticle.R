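test_that("sub-particle offsets match the rotation-matrix oracle and are linear", {
  set.seed(81)
  recs <- data.frame(rot = runif(20, 0, 360), tilt = sample(c(90, 270), 20, TRUE),
                     psi = runif(20, 0, 360), sx = runif(20, -4, 4),
                     sy = runif(20, -4, 4), defocus = 10000)
  pts <- data.frame(x = runif(50, -150, 150), y = runif(50, -150, 150),
                    z = runif(50, -100, 100))
  off <- compute_subparticle_offsets(pts, recs, pixel_size = 4)
  expect_equal(nrow(off), 1000)
  for (k in sample(nrow(off), 60)) {
    i <- off$particle[k]; t <- off$point[k]
    R <- rotation_matrix(euler(recs$rot[i], recs$tilt[i], recs$psi[i]))
    q <- R %*% c(pts$x[t], pts$y[t], pts$z[t])
    expect_lt(max(abs(c(off$off_x[k], off$off_y[k]) -
                        (q[1:2] / 4 + c(recs$sx[i], recs$sy[i])))), 1e-9)
    expect_equal(off$rot[k],
                 (recs$rot[i] + atan2(pts$y[t], pts$x[t]) * 180 / pi) %% 360,
                 tolerance = 1e-9)
  }
  # p = origin: offset equals the particle shift, rot unchanged
  o0 <- compute_subparticle_offsets(data.frame(x = 0, y = 0, z = 0), recs, 4)
  expect_equal(o0$off_x, recs$sx, tolerance = 1e-12)
  expect_equal(o0$off_y, recs$sy, tolerance = 1e-12)
  # linearity in p
  p1 <- c(40, -20, 30); p2 <- c(-10, 50, -60)
  oa <- compute_subparticle_offsets(rbind(p1), recs, 4)
  ob <- compute_subparticle_offsets(rbind(p2), recs, 4)
  oab <- compute_subparticle_offsets(rbind(p1 + p2), recs, 4)
  expect_equal(oab$off_x, oa$off_x + ob$off_x - recs$sx, tolerance = 1e-9)
  expect_equal(oab$off_y, oa$off_y + ob$off_y - recs$sy, tolerance = 1e-9)
})

test_that("the nine-offset scheme yields exactly nine sub-images per particle", {
  spec <- tl_spec()
  pts <- lattice_contact_points(spec)
  expect_equal(nrow(pts), 9)
  set.seed(83)
  m <- 7
  stack <- image_stack(array(rnorm(128 * 128 * m), dim = c(128, 128, m)), 4)
  recs <- data.frame(rot = runif(m, 0, 360), tilt = 90, psi = runif(m, 0, 360),
                     sx = 0, sy = 0, defocus = 9000)
  off <- compute_subparticle_offsets(pts, recs, 4)
  sub <- extract_subparticles(stack, off, box = 64, boundary = "pad_mean")
  expect_equal(n_images(sub), 9 * m)
})

test_that("extraction crops where requested and honors the boundary policy", {
  n <- 64
  img <- matrix(0, n, n)
  img[41, 45] <- 1        # impulse at centered coords (8, 12)
  stack <- image_stack(img, 2)
  off <- data.frame(particle = 1, point = 1, off_x = 8, off_y = 12)
  sub <- extract_subparticles(stack, off, box = 16)
  pk <- which(sub$data[, , 1] == max(sub$data[, , 1]), arr.ind = TRUE)
  expect_equal(as.integer(pk), c(9, 9))   # box/2 + 1: centered
  # identity crop
  off0 <- data.frame(particle = 1, point = 1, off_x = 0, off_y = 0)
  sub0 <- extract_subparticles(stack, off0, box = n)
  expect_equal(sub0$data[, , 1], img, tolerance = 1e-9)
  # boundary error names the particle
  offb <- data.frame(particle = 1, point = 2, off_x = 30, off_y = 0)
  expect_error(extract_subparticles(stack, offb, box = 16),
               regexp = "particle 1", class = "tl_out_of_bounds")
})

test_that("impulse round-trip through the sub-particle chain lands centered", {
  # an impulse placed at p in the volume must reconstruct to within one
  # voxel of the sub-box center after compute -> extract -> reconstruct
  n <- 64; ps <- 4
  p <- c(60, 80, -24)
  v <- array(0, dim = rep(n, 3))
  buf <- as.numeric(v)
  tubelattice:::add_blob(buf, n, p, 6, 1, ps)
  vol <- density_volume(array(buf, dim = rep(n, 3)), ps)
  set.seed(85)
  m <- 40
  recs <- data.frame(rot = runif(m, 0, 360), tilt = 90, psi = runif(m, 0, 360),
                     sx = runif(m, -3, 3), sy = runif(m, -3, 3))
  dat <- array(0, dim = c(n, n, m))
  for (i in 1:m)
    dat[, , i] <- rotate_project(vol, euler(recs$rot[i], recs$tilt[i], recs$psi[i]),
                                 c(recs$sx[i], recs$sy[i]))
  stack <- image_stack(dat, ps)
  off <- compute_subparticle_offsets(data.frame(x = p[1], y = p[2], z = p[3]),
                                     recs, ps)
  sub <- extract_subparticles(stack, off, box = 32, boundary = "pad_mean")
  rec <- reconstruct_backproject(sub, off)
  w <- which(rec$data == max(rec$data), arr.ind = TRUE)
  expect_lt(max(abs(w - 17)), 1.01)   # center voxel of the 32-box
})

test_that("contact-site reconstruction shows the membrane bridge only when stacked", {
  opt <- tl_optics()
  bridge_ratio <- function(stacked_fraction) {
    # walk-free lattice so the center contact sits at the model coordinate
    sp <- tl_spec(stacked_fraction = stacked_fraction, spacing_jitter_sd = 2,
                  azimuthal_walk_sd = 0)
    sim <- simulate_particles(sp, opt, 60, noise_sd = 0, seed = 87)
    pts <- lattice_contact_points(sp)
    # ground-truth orientations stand in for a refined alignment
    off <- compute_subparticle_offsets(pts, sim$records, opt$pixel_size)
    sub <- extract_subparticles(sim$stack, off, box = 64, boundary = "pad_mean")
    rec <- reconstruct_backproject(sub, off, ctf_mode = "phase_flip",
                                   optics = opt)
    ax <- (seq_len(64) - 33) * opt$pixel_size
    xb <- ax >= -10 & ax <= 0               # outer leaflet to VD radius
    z0 <- median(rec$data)                  # map pedestal
    bridge <- mean(rec$data[xb, abs(ax) <= 8, abs(ax) <= 8]) - z0
    # same radial band, displaced between the contact columns and rungs
    bg <- mean(rec$data[xb, ax >= 16 & ax <= 36, ax >= 15 & ax <= 35]) - z0
    bridge / max(bg, 1e-4)
  }
  expect_gt(bridge_ratio(1), 3)
  expect_lt(bridge_ratio(0), 1.5)
})
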