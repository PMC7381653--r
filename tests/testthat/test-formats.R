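test_that("tlt files round-trip and malformed input is rejected", {
  f <- withr::local_tempfile(fileext = ".tlt")
  writeLines(c("0.0", "3.0", "-3.0"), f)
  expect_equal(read_tlt(f), c(0, 3, -3))

  angles <- seq(-60, 60, by = 3)
  write_tlt(angles, f)
  got <- read_tlt(f)
  expect_length(got, 41)
  expect_equal(got, angles)

  writeLines(character(0), f)
  expect_error(read_tlt(f), "empty")
  writeLines(c("1.0", "oops"), f)
  expect_error(read_tlt(f), "line 2")
  expect_error(read_tlt(file.path(tempdir(), "nope.tlt")), "no such file")
})

test_that("xf files parse the 6-number affine convention", {
  f <- withr::local_tempfile(fileext = ".xf")
  writeLines("1 0 0 1 0 0", f)
  r <- read_xf(f)[[1]]
  expect_equal(r$A, diag(2))
  expect_equal(r$shift, c(0, 0))

  writeLines("0 1 -1 0 5 -2", f)
  r <- read_xf(f)[[1]]
  expect_equal(r$A, matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE))
  expect_equal(r$shift, c(5, -2))

  writeLines("1 0 0 1 0", f)
  expect_error(read_xf(f), "6 numbers")

  xf <- list(list(A = matrix(c(0.98, 0.17, -0.17, 0.98), 2, 2),
                  shift = c(12.5, -3.25)),
             list(A = diag(2), shift = c(0, 0)))
  write_xf(xf, f)
  back <- read_xf(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$A, xf[[1]]$A, tolerance = 1e-6)
  expect_equal(back[[1]]$shift, xf[[1]]$shift, tolerance = 1e-5)
})

test_that("particle tables follow the 26-column convention and round-trip", {
  tb <- particle_table(positions = c(100, 100, 50))
  expect_s3_class(tb, "dynamo_table")
  expect_equal(tb$tag, 1L)
  expect_equal(c(tb$dx, tb$dy, tb$dz), c(0, 0, 0))
  expect_equal(c(tb$tdrot, tb$tilt, tb$narot), c(0, 0, 0))
  expect_equal(c(tb$x, tb$y, tb$z), c(100, 100, 50))

  set.seed(11)
  tb10 <- particle_table(matrix(runif(30, 10, 400), 10, 3),
                         shifts = matrix(rnorm(30), 10, 3),
                         eulers = matrix(runif(30, -180, 180), 10, 3),
                         score = runif(10))
  f <- withr::local_tempfile(fileext = ".tbl")
  write_particle_table(tb10, f)
  back <- read_particle_table(f)
  expect_equal(nrow(back), 10)
  m0 <- as.matrix(as.data.frame(tb10))
  m1 <- as.matrix(as.data.frame(back))
  expect_lt(max(abs(m1 - m0) / pmax(1, abs(m0))), 1e-5)

  writeLines(paste(rep("1", 20), collapse = " "), f)
  expect_error(read_particle_table(f), "at least 26")
  writeLines(paste(c(rep("1", 25), "x"), collapse = " "), f)
  expect_error(read_particle_table(f), "non-numeric")
})

test_that("extra particle-table columns are preserved opaquely", {
  tb <- particle_table(matrix(runif(9, 50, 200), 3, 3))
  df <- as.data.frame(tb)
  df$c27 <- c(7, 8, 9)
  df$c28 <- c(0.1, 0.2, 0.3)
  f <- withr::local_tempfile(fileext = ".tbl")
  write_particle_table(df, f)
  back <- read_particle_table(f)
  expect_equal(ncol(back), 28)
  expect_equal(back$c27, c(7, 8, 9))
  expect_equal(back$c28, c(0.1, 0.2, 0.3), tolerance = 1e-6)
})

test_that("STAR particle files round-trip field-for-field", {
  ctf <- ctf_model(defocus_u = 40000, pixel_size = 1.7)
  p1 <- data.frame(tag = 1L, coord_x = 256, coord_y = 256, rot = 0,
                   tilt = 0, psi = 0, defocus_u = 40000, defocus_v = 40000,
                   defocus_angle = 0, z_offset = 0, halfset = 1L,
                   micrograph = "high_dose.mrc", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".star")
  write_star(p1, ctf, f)
  back <- read_star_particles(f)
  expect_equal(back$particles$defocus_u, 40000)
  expect_equal(back$particles$coord_x, 256)
  expect_equal(back$particles$rot, 0)
  expect_equal(back$optics$rlnVoltage, 300)
  expect_equal(back$optics$rlnAmplitudeContrast, 0.07)

  expect_error(write_star(data.frame(), ctf, f), "empty")
})

test_that("STAR half-set partition and row counts are conserved", {
  set.seed(3)
  n <- 2563
  p <- data.frame(tag = seq_len(n),
                  coord_x = runif(n, 100, 900),
                  coord_y = runif(n, 100, 900),
                  rot = runif(n, -180, 180), tilt = runif(n, 0, 180),
                  psi = runif(n, -180, 180),
                  defocus_u = runif(n, 30000, 50000),
                  defocus_v = runif(n, 30000, 50000),
                  defocus_angle = 0, z_offset = rnorm(n, 0, 40),
                  halfset = sample(1:2, n, TRUE),
                  micrograph = "hd.mrc", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".star")
  write_star(p, ctf_model(), f)
  back <- read_star_particles(f)$particles
  expect_equal(nrow(back), n)
  expect_identical(back$halfset, p$halfset)
  expect_lt(max(abs(back$coord_x - p$coord_x)), 1e-5)
})

test_that("MRC images and volumes round-trip with voxel size", {
  f <- withr::local_tempfile(fileext = ".mrc")
  img <- matrix(as.numeric(1:(64 * 64)), 64, 64)
  write_mrc(img, 2.2, f)
  m <- read_mrc(f)
  expect_equal(m$data, img)
  expect_equal(m$voxel_size, rep(2.2, 3), tolerance = 1e-6)

  vol <- array(stats::rnorm(32^3), c(32, 32, 32))
  write_mrc(vol, 1.1, f)
  m <- read_mrc(f)
  expect_equal(dim(m$data), c(32, 32, 32))
  expect_lt(max(abs(m$data - vol)), 1e-5)
  expect_equal(m$voxel_size, rep(1.1, 3), tolerance = 1e-6)
})

test_that("non-MRC and truncated files are rejected", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(1, 2048)), f)
  expect_error(read_mrc(f), "MAP magic")

  img <- matrix(as.numeric(1:1024), 32, 32)
  write_mrc(img, 1, f)
  full <- readBin(f, "raw", n = file.size(f))
  writeBin(full[1:(length(full) - 512)], f)
  expect_error(read_mrc(f), "truncated")
})

test_that("tilt alignments validate record counts and singular affines", {
  xf <- rep(list(list(A = diag(2), shift = c(0, 0))), 3)
  expect_error(tilt_alignment(c(0, 3), xf, c(512, 512), c(256, 256, 64)),
               "!=")
  bad <- xf
  bad[[2]]$A <- matrix(0, 2, 2)
  expect_error(tilt_alignment(c(-3, 0, 3), bad, c(512, 512),
                              c(256, 256, 64)), "singular")
  al <- tilt_alignment(c(-3, 0, 3), xf, c(512, 512), c(256, 256, 64))
  expect_equal(zero_tilt_index(al), 2L)
  al2 <- tilt_alignment(c(-6, -3, 3), xf, c(512, 512), c(256, 256, 64))
  expect_error(zero_tilt_index(al2), "no zero-tilt")
})
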