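test_that("rotation matrices follow the ZYZ convention and are orthonormal", {
  expect_equal(rotation_matrix(euler(0, 0, 0)), diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(rotation_matrix(euler(90, 0, 0)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    e <- euler(runif(1, 0, 360), runif(1, 0, 360), runif(1, 0, 360))
    R <- rotation_matrix(e)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    # periodicity in each angle
    e2 <- euler(e[["rot"]] + 360, e[["tilt"]] - 360, e[["psi"]] + 720)
    expect_lt(max(abs(rotation_matrix(e2) - R)), 1e-10)
  }
  expect_error(euler(NaN, 0, 0), class = "tl_invalid_argument")
})

test_that("tilt-270 orientations are the mirrored tilt-90 view", {
  # R(rot, 270, psi) = diag(1, -1, -1) R(rot, 90, 180 - psi)
  set.seed(4)
  for (i in 1:20) {
    rot <- runif(1, 0, 360); psi <- runif(1, 0, 360)
    R270 <- rotation_matrix(euler(rot, 270, psi))
    nt <- normalize_tilt(euler(rot, 270, psi))
    expect_true(nt$mirror_y)
    R90 <- rotation_matrix(nt$euler)
    expect_lt(max(abs(R270 - diag(c(1, -1, -1)) %*% R90)), 1e-10)
  }
})

test_that("projection places impulses where project_point predicts", {
  n <- 32; ps <- 2
  set.seed(21)
  for (rep in 1:5) {
    ijk <- sample(10:22, 3)
    v <- array(0, dim = rep(n, 3)); v[ijk[1], ijk[2], ijk[3]] <- 1
    vol <- density_volume(v, ps)
    p <- (ijk - (n / 2 + 1)) * ps
    e <- euler(runif(1, 0, 360), runif(1, 0, 360), runif(1, 0, 360))
    sh <- runif(2, -3, 3)
    img <- rotate_project(vol, e, sh)
    pred <- project_point(p, e, sh, ps) + n / 2 + 1
    w <- img / sum(img)
    centroid <- c(sum(row(img) * w), sum(col(img) * w))
    expect_lt(max(abs(centroid - pred)), 0.25)
  }
  # identity projection is the z-sum
  v <- array(rnorm(16^3), dim = rep(16, 3))
  vol <- density_volume(v, 1)
  expect_equal(rotate_project(vol, euler(0, 0, 0)), apply(v, c(1, 2), sum),
               tolerance = 1e-9)
})

test_that("project_point matches the rotation-matrix oracle at 1e-9", {
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(3, -80, 80)
    e <- euler(runif(1, 0, 360), runif(1, 0, 360), runif(1, 0, 360))
    sh <- runif(2, -5, 5)
    ps <- runif(1, 1, 5)
    q <- rotation_matrix(e) %*% p
    expect_lt(max(abs(project_point(p, e, sh, ps) - (q[1:2] / ps + sh))), 1e-9)
  }
  expect_equal(as.numeric(project_point(c(0, 0, 0), euler(10, 20, 30),
                                        c(1.5, -2), 3)), c(1.5, -2))
  # Ry(90) sends (r, 0, 0) to (0, 0, -r): projects onto the origin
  expect_equal(as.numeric(project_point(c(50, 0, 0), euler(0, 90, 0),
                                        c(0, 0), 2)), c(0, 0),
               tolerance = 1e-12)
  expect_error(project_point(c(1, 1, 1), euler(), c(0, 0), -1),
               class = "tl_invalid_argument")
})

test_that("projection is linear and backprojection is its adjoint", {
  n <- 24
  set.seed(41)
  A <- array(rnorm(n^3), dim = rep(n, 3))
  B <- array(rnorm(n^3), dim = rep(n, 3))
  e <- euler(33, 70, 110); sh <- c(1.2, -0.7)
  pa <- rotate_project(density_volume(A, 2), e, sh)
  pb <- rotate_project(density_volume(B, 2), e, sh)
  pab <- rotate_project(density_volume(A + B, 2), e, sh)
  expect_equal(pab, pa + pb, tolerance = 1e-6)
  for (i in 1:5) {
    e <- euler(runif(1, 0, 360), runif(1, 0, 360), runif(1, 0, 360))
    sh <- runif(2, -2, 2)
    I <- matrix(rnorm(n^2), n, n)
    P <- tubelattice:::cpp_project(as.vector(A), n, rotation_matrix(e),
                                   sh[1], sh[2])
    bt <- numeric(n^3)
    tubelattice:::cpp_backproject_add(bt, n, I, rotation_matrix(e),
                                      sh[1], sh[2])
    expect_lt(abs(sum(P * I) - sum(A * bt)) / abs(sum(P * I)), 1e-4)
  }
})

test_that("backprojection reconstructs a phantom from many views", {
  ps <- 4
  vol <- make_phantom(48, ps)
  set.seed(51)
  m <- 400
  recs <- data.frame(rot = runif(m, 0, 360),
                     tilt = acos(runif(m, -1, 1)) * 180 / pi,
                     psi = runif(m, 0, 360), sx = 0, sy = 0)
  dat <- array(0, dim = c(48, 48, m))
  for (i in seq_len(m))
    dat[, , i] <- rotate_project(vol, euler(recs$rot[i], recs$tilt[i], recs$psi[i]),
                                 wrap_z = FALSE)
  stack <- image_stack(dat, ps)
  rec <- reconstruct_backproject(stack, recs, wrap_z = FALSE)
  fsc <- compute_fsc(rec, vol)
  # high fidelity out to 3x the Nyquist period (period 24 A here)
  keep <- fsc$freq <= 1 / (6 * ps)
  expect_true(all(fsc$fsc[keep] >= 0.9))
  # duplicating every particle leaves the normalized reconstruction unchanged
  stack2 <- image_stack(array(c(dat, dat), dim = c(48, 48, 2 * m)), ps)
  rec2 <- reconstruct_backproject(stack2, rbind(recs, recs), wrap_z = FALSE)
  expect_equal(rec2$data, rec$data, tolerance = 1e-6)
  expect_error(reconstruct_backproject(image_stack(array(0, c(8, 8, 0)), 1),
                                       recs[0, ]),
               class = "tl_invalid_argument")
})

test_that("single-image adjoint consistency: z-sum of backprojection matches", {
  n <- 32
  set.seed(61)
  I <- matrix(0, n, n)
  I[10:20, 12:24] <- rnorm(11 * 13)
  stack <- image_stack(I, 2)
  rec <- reconstruct_backproject(stack, data.frame(rot = 0, tilt = 0, psi = 0,
                                                   sx = 0, sy = 0),
                                 weight = "none")
  zs <- apply(rec$data, c(1, 2), sum)
  # raw adjoint smears the image along z; its z-sum reproduces the image
  expect_gt(ncc(zs, I), 0.999)
})
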