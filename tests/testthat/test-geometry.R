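test_that("ZXZ matrices equal the literal textbook product", {
  expect_equal(zxz_to_matrix(0, 0, 0), diag(3))
  # degenerate tilt = 0: both Z rotations act about the same axis
  expect_equal(zxz_to_matrix(90, 0, 0), zxz_to_matrix(0, 0, 90),
               tolerance = 1e-12)
  expect_equal(zxz_to_matrix(30, 40, 50), oracle_zxz(30, 40, 50),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    e <- runif(3, -360, 360)
    expect_equal(zxz_to_matrix(e[1], e[2], e[3]),
                 oracle_zxz(e[1], e[2], e[3]), tolerance = 1e-12)
    expect_equal(zyz_to_matrix(e[1], e[2], e[3]),
                 oracle_zyz(e[1], e[2], e[3]), tolerance = 1e-12)
  }
})

test_that("ZYZ decomposition reconstructs 1000 random rotations to 1e-9", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    e <- matrix_to_zyz(R)
    back <- zyz_to_matrix(e[["rot"]], e[["tilt"]], e[["psi"]])
    worst <- max(worst, max(abs(back - R)))
    expect_gte(e[["tilt"]], 0)
    expect_lte(e[["tilt"]], 180)
  }
  expect_lt(worst, 1e-9)
})

test_that("ZXZ decomposition inverts zxz_to_matrix", {
  set.seed(43)
  for (i in 1:200) {
    R <- random_rotation()
    e <- matrix_to_zxz(R)
    expect_equal(zxz_to_matrix(e[["tdrot"]], e[["tilt"]], e[["narot"]]), R,
                 tolerance = 1e-9)
  }
})

test_that("gimbal-lock tie-break folds in-plane rotation into psi", {
  e <- matrix_to_zyz(rot_z(25))
  expect_equal(e[["rot"]], 0)
  expect_equal(e[["tilt"]], 0)
  expect_equal(e[["psi"]], 25, tolerance = 1e-9)
  expect_equal(matrix_to_zyz(diag(3)), c(rot = 0, tilt = 0, psi = 0))
  expect_error(matrix_to_zyz(matrix(1, 3, 3)), "orthonormal")
})

make_align <- function(angles = c(-3, 0, 3), A = diag(2),
                       shift = c(0, 0), image_size = c(512, 512),
                       tomogram_size = c(256, 256, 64), binning = 1) {
  # the .xf stores raw->aligned; store the inverse of the transform we want
  # applied so projection_geometry() recovers it
  Ai <- solve(A)
  xf <- rep(list(list(A = Ai, shift = as.numeric(-Ai %*% shift))),
            length(angles))
  tilt_alignment(angles, xf, image_size, tomogram_size, binning)
}

test_that("composed rotations equal the brute-force elementary product", {
  g0 <- projection_geometry(make_align())
  expect_equal(compose_pose(list(tdrot = 0, tilt = 0, narot = 0), g0),
               diag(3), tolerance = 1e-12)

  # zero tilt + identity alignment: pure ZXZ -> ZYZ relabelling
  pose <- list(tdrot = 31, tilt = 57, narot = -112)
  expect_equal(matrix_to_zyz(compose_pose(pose, g0)),
               matrix_to_zyz(oracle_zxz(31, 57, -112)), tolerance = 1e-9)

  g15 <- projection_geometry(make_align(A = rot_z(15)[1:2, 1:2]))
  expect_equal(compose_pose(list(tdrot = 30, tilt = 40, narot = 50), g15),
               oracle_rz(15) %*% oracle_zxz(30, 40, 50), tolerance = 1e-9)

  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    phi <- runif(1, -180, 180)
    stage <- runif(1, -60, 60)
    e <- runif(3, -360, 360)
    al <- make_align(angles = c(stage - 3, stage, stage + 3),
                     A = rot_z(phi)[1:2, 1:2])
    g <- projection_geometry(al, image = 2)
    got <- compose_pose(list(tdrot = e[1], tilt = e[2], narot = e[3]), g)
    want <- oracle_rz(phi) %*% oracle_ry(stage) %*%
      oracle_zxz(e[1], e[2], e[3])
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("mirror affines are rejected in pose composition", {
  al <- make_align(A = matrix(c(1, 0, 0, -1), 2, 2))
  g <- projection_geometry(al)
  expect_error(compose_pose(list(tdrot = 0, tilt = 0, narot = 0), g),
               "mirror")
})

test_that("position mapping follows the centre/binning/affine chain", {
  g <- projection_geometry(make_align())
  ctr_pose <- list(x = 128.5, y = 128.5, z = 32.5, dx = 0, dy = 0, dz = 0)
  m <- map_position(ctr_pose, g)
  expect_equal(m$xy, c(255.5, 255.5))   # micrograph centre, 0-based
  expect_equal(m$z_offset, 0)

  # offset (10, 0, 0) through a 90-degree in-plane rotation -> (0, 10)
  g90 <- projection_geometry(make_align(A = rot_z(90)[1:2, 1:2]))
  m <- map_position(list(x = 138.5, y = 128.5, z = 32.5,
                         dx = 0, dy = 0, dz = 0), g90)
  expect_equal(m$xy, c(255.5, 255.5) + c(0, 10), tolerance = 1e-9)

  # oracle: explicit affine application with shift, binning and stage tilt
  al <- make_align(angles = c(-3, 0, 3), A = rot_z(25)[1:2, 1:2],
                   shift = c(7, -4), binning = 2)
  g <- projection_geometry(al)
  pose <- list(x = 140, y = 100, z = 40, dx = 1.5, dy = -2, dz = 0.5)
  cc <- c(141.5, 98, 40.5) - (c(256, 256, 64) + 1) / 2
  q <- cc[1:2] * 2
  want <- as.numeric(rot_z(25)[1:2, 1:2] %*% q) + c(7, -4) +
    (c(512, 512) - 1) / 2
  m <- map_position(pose, g)
  expect_equal(m$xy, want, tolerance = 1e-9)
  expect_equal(m$z_offset, cc[3])
})

test_that("z offsets follow the stage tilt rotation", {
  al <- make_align(angles = c(27, 30, 33))
  g <- projection_geometry(al, image = 2)
  pose <- list(x = 160, y = 128.5, z = 40, dx = 0, dy = 0, dz = 0)
  cc <- c(160, 128.5, 40) - (c(256, 256, 64) + 1) / 2
  want <- as.numeric(oracle_ry(30) %*% cc)
  m <- map_position(pose, g)
  expect_equal(m$z_offset, want[3], tolerance = 1e-9)
  expect_equal(m$xy, want[1:2] + (c(512, 512) - 1) / 2, tolerance = 1e-9)
})

test_that("export produces one record per in-bounds particle", {
  sc <- simulate_scenario(n_particles = 30, seed = 5)
  ctf <- ctf_model(pixel_size = 1.7)
  res <- export_particles(sc$table, sc$align, 40000, ctf, box_size = 64)
  expect_equal(nrow(res$particles), 30)
  expect_equal(nrow(res$rejected), 0)
  expect_setequal(res$particles$halfset, 1:2)

  # particle near the edge (inside the micrograph, but closer than half a
  # box) must land in the rejection list with a reason
  tb <- particle_table(rbind(c(240, 240, 32.5),
                             c(9, 9, 32.5)))   # projects ~8 px from edge
  al <- make_align(tomogram_size = c(512, 512, 64))
  res <- export_particles(tb, al, 40000, ctf, box_size = 64)
  expect_equal(nrow(res$particles), 1)
  expect_equal(nrow(res$rejected), 1)
  expect_equal(res$rejected$tag, 2L)
  expect_equal(res$rejected$reason, "out_of_bounds")
  # conservation: every particle in exactly one of the two lists
  expect_setequal(c(res$particles$tag, res$rejected$tag), tb$tag)
})

test_that("export without a zero-tilt image fails loudly", {
  sc <- simulate_scenario(n_particles = 3, seed = 6)
  al <- sc$align
  al$angles <- al$angles + 1.5
  expect_error(export_particles(sc$table, al, 40000, ctf_model()),
               "no zero-tilt")
})

test_that("per-particle defocus tracks Z-height through export", {
  sc <- simulate_scenario(n_particles = 25, seed = 7)
  ctf <- ctf_model(pixel_size = 1.7)
  res <- export_particles(sc$table, sc$align, 40000, ctf)
  voxel <- 1.7 * sc$align$binning
  expect_equal(res$particles$defocus_u,
               40000 + res$particles$z_offset * voxel, tolerance = 1e-9)
  expect_equal(res$particles$z_offset, sc$truth$z_offset,
               tolerance = 1e-9)
})
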