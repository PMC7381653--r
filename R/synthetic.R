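# Synthetic phantom scenario: a fully specified stand-in for a real
# tilt-series acquisition (hybrid scheme, IMOD-style alignment, Dynamo-style
# particle table, rendered high-dose micrograph) with exact ground truth, so
# the geometric conventions of the export chain can be validated end to end
# without any deposited data.

# Asymmetric tri-lobe marker: three Gaussian lobes in the reference XY
# plane. Lobe centres are chosen with zero centre of mass and zero XY
# covariance cross-term, and per-lobe masses are equal (amplitude ~
# 1/width^2), so the rendered intensity has (a) centroid exactly at the
# particle position and (b) principal axis exactly along +X — both position
# and in-plane orientation are observable from the image. The differing
# lobe widths make the marker asymmetric (no mirror/rotational symmetry of
# appearance).
.marker_spec <- function() {
  data.frame(x = c(6, -3, -3), y = c(0, 2.4, -2.4), z = c(0, 0, 0),
             width = c(1.0, 1.4, 0.7))
}

.rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# quaternion -> rotation matrix (unit q = (w, x, y, z))
.quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    3, 3)
}

#' Generate a synthetic hybrid-acquisition scenario
#'
#' Builds a hybrid dose scheme, a tilt-series alignment whose zero-tilt
#' in-plane transform is a known rotation + shift, a particle table with
#' uniformly random in-bounds positions and orientations, and the high-dose
#' zero-tilt micrograph with an asymmetric tri-lobe marker rendered at every
#' projected particle position. The rendering re-derives the
#' tomogram-to-micrograph mapping with explicit inline arithmetic, so it is
#' an independent oracle for the geometry module rather than a call into it.
#'
#' Orientations: \code{"uniform"} samples rotations uniformly on SO(3) via
#' random unit quaternions (no Euler-space bias); \code{"inplane"} samples
#' tilt-free poses (random tdrot/narot, tilt = 0), for which the projected
#' marker is an exact 2D rotation of the reference marker and the in-plane
#' angle is directly comparable to the exported psi.
#'
#' @param n_particles number of particles.
#' @param tomogram_size length-3, voxels.
#' @param micrograph_size length-2, pixels.
#' @param binning micrograph pixels per tomogram voxel edge.
#' @param inplane_rotation rotation angle (degrees) of the zero-tilt
#'   alignment transform.
#' @param inplane_shift length-2 shift (pixels) of that transform.
#' @param noise_sigma additive Gaussian noise on the micrograph.
#' @param seed RNG seed; identical seeds give bitwise-identical scenarios.
#' @param orientations "uniform" or "inplane" (see Details).
#' @param marker_sigma Gaussian lobe width of the marker, pixels.
#' @param min_separation minimum distance between projected particles,
#'   pixels (keeps extraction boxes uncontaminated).
#' @param edge_margin minimum distance of projected particles from the
#'   micrograph edge, pixels.
#' @return object of class \code{hs_scenario}: \code{scheme}, \code{align},
#'   \code{table} (ground-truth Dynamo-style table), \code{truth}
#'   (data.frame with projected positions \code{mic_x/mic_y} and expected
#'   \code{psi} for in-plane scenarios), \code{micrograph}, \code{config}.
#' @export
simulate_scenario <- function(n_particles = 100,
                              tomogram_size = c(480, 480, 120),
                              micrograph_size = c(1024, 1024),
                              binning = 2,
                              inplane_rotation = 0,
                              inplane_shift = c(0, 0),
                              noise_sigma = 0,
                              seed = 1,
                              orientations = c("uniform", "inplane"),
                              marker_sigma = 3,
                              min_separation = 60,
                              edge_margin = 48) {
  orientations <- match.arg(orientations)
  stopifnot(n_particles >= 1, binning > 0)
  set.seed(seed)

  scheme <- make_scheme(-60, 60, 3, total_dose = 95, hybrid = TRUE,
                        high_dose = 15)
  angles <- sort(scheme$angle)
  A_app <- .rot2(inplane_rotation)
  sh_app <- as.numeric(inplane_shift)
  # .xf stores raw -> aligned; the applied (aligned -> raw) transform above
  # is therefore recorded as its inverse.
  A_xf <- solve(A_app)
  sh_xf <- as.numeric(-A_xf %*% sh_app)
  xf <- rep(list(list(A = A_xf, shift = sh_xf)), length(angles))
  align <- tilt_alignment(angles, xf, micrograph_size, tomogram_size,
                          binning)

  ctr_t <- (tomogram_size + 1) / 2
  ctr_m <- (micrograph_size - 1) / 2
  project <- function(pos) {      # independent inline chain, zero tilt
    cc <- pos - ctr_t
    as.numeric(A_app %*% (cc[1:2] * binning)) + sh_app + ctr_m
  }

  # rejection-sample positions whose projections are in bounds + separated
  pos <- matrix(NA_real_, n_particles, 3)
  mic <- matrix(NA_real_, n_particles, 2)
  zmargin <- 8
  attempts <- 0L
  for (i in seq_len(n_particles)) {
    ok <- FALSE
    for (a in seq_len(1000)) {
      attempts <- attempts + 1L
      p <- c(stats::runif(1, 1, tomogram_size[1]),
             stats::runif(1, 1, tomogram_size[2]),
             stats::runif(1, zmargin, tomogram_size[3] - zmargin))
      m <- project(p)
      if (any(m < edge_margin) ||
          any(m > micrograph_size - 1 - edge_margin)) next
      if (i > 1) {
        d2 <- (mic[seq_len(i - 1), 1] - m[1])^2 +
          (mic[seq_len(i - 1), 2] - m[2])^2
        if (min(d2) < min_separation^2) next
      }
      pos[i, ] <- p; mic[i, ] <- m; ok <- TRUE
      break
    }
    if (!ok)
      stop("particle density too high: could not place particle ", i,
           " after 1000 attempts")
  }

  eulers <- matrix(0, n_particles, 3)
  if (orientations == "uniform") {
    for (i in seq_len(n_particles)) {
      R <- .quat_to_matrix(stats::rnorm(4))
      eulers[i, ] <- matrix_to_zxz(R)
    }
  } else {
    eulers[, 1] <- stats::runif(n_particles, 0, 360)   # tdrot
    eulers[, 3] <- stats::runif(n_particles, 0, 360)   # narot
  }

  # render: blob k of particle i sits at the projection of the pose-rotated
  # marker point (orthographic at zero tilt)
  mk <- .marker_spec()
  img <- matrix(0, micrograph_size[1], micrograph_size[2])
  for (i in seq_len(n_particles)) {
    Rp <- zxz_to_matrix(eulers[i, 1], eulers[i, 2], eulers[i, 3])
    for (k in seq_len(nrow(mk))) {
      v <- as.numeric(Rp %*% c(mk$x[k], mk$y[k], mk$z[k]))
      b <- mic[i, ] + as.numeric(A_app %*% (v[1:2] * binning))
      sk <- marker_sigma * mk$width[k]
      amp <- 1 / mk$width[k]^2        # equal lobe mass
      w <- ceiling(4 * sk)
      x0 <- max(0, floor(b[1]) - w); x1 <- min(micrograph_size[1] - 1,
                                               ceiling(b[1]) + w)
      y0 <- max(0, floor(b[2]) - w); y1 <- min(micrograph_size[2] - 1,
                                               ceiling(b[2]) + w)
      xs <- x0:x1; ys <- y0:y1
      g <- amp * exp(-outer((xs - b[1])^2, (ys - b[2])^2, "+") /
                       (2 * sk^2))
      img[xs + 1, ys + 1] <- img[xs + 1, ys + 1] + g
    }
  }
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                        nrow(img), ncol(img))

  table <- particle_table(positions = pos, eulers = eulers)
  psi_true <- if (orientations == "inplane")
    ((eulers[, 1] + eulers[, 3] + inplane_rotation + 180) %% 360) - 180
  else rep(NA_real_, n_particles)
  truth <- data.frame(tag = table$tag,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      tdrot = eulers[, 1], tilt = eulers[, 2],
                      narot = eulers[, 3],
                      mic_x = mic[, 1], mic_y = mic[, 2],
                      z_offset = pos[, 3] - ctr_t[3],
                      psi = psi_true)
  structure(list(
    scheme = scheme, align = align, table = table, truth = truth,
    micrograph = img,
    config = list(n_particles = n_particles,
                  tomogram_size = tomogram_size,
                  micrograph_size = micrograph_size, binning = binning,
                  inplane_rotation = inplane_rotation,
                  inplane_shift = inplane_shift,
                  noise_sigma = noise_sigma, seed = seed,
                  orientations = orientations,
                  marker_sigma = marker_sigma,
                  min_separation = min_separation,
                  edge_margin = edge_margin)),
    class = "hs_scenario")
}

#' @export
print.hs_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "hs_scenario: %d particles (%s orientations), tomogram %s, micrograph %s, binning %g, seed %d\n",
    cfg$n_particles, cfg$orientations,
    paste(cfg$tomogram_size, collapse = "x"),
    paste(cfg$micrograph_size, collapse = "x"), cfg$binning, cfg$seed))
  invisible(x)
}

#' Write a scenario out as a fixture directory
#'
#' Emits the complete on-disk face of the scenario: tilt angles (.tlt),
#' alignment transforms (.xf), the particle table (.tbl), the high-dose
#' micrograph (MRC) and the ground truth (STAR table).
#'
#' @param scenario an \code{hs_scenario}.
#' @param dir output directory (created if missing).
#' @param pixel_size micrograph pixel size written into the MRC header.
#' @return the directory, invisibly.
#' @export
write_scenario <- function(scenario, dir, pixel_size = 1.7) {
  stopifnot(inherits(scenario, "hs_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tlt(scenario$align$angles, file.path(dir, "series.tlt"))
  write_xf(scenario$align$xf, file.path(dir, "series.xf"))
  write_particle_table(scenario$table, file.path(dir, "particles.tbl"))
  write_mrc(scenario$micrograph, pixel_size,
            file.path(dir, "high_dose.mrc"))
  con <- file(file.path(dir, "truth.star"), "wt")
  .write_star_loop(con, "truth", scenario$truth)
  close(con)
  invisible(dir)
}

#' Windowed intensity centroid around a point
#'
#' Intensity-weighted centroid of the pixels within \code{radius} of
#' \code{centre} (0-based coordinates); negative values are clipped to zero
#' so additive noise does not destabilize the weighting.
#'
#' @param image numeric matrix.
#' @param centre length-2 numeric, 0-based pixel coordinates.
#' @param radius window radius, pixels.
#' @return length-2 numeric centroid (0-based).
#' @export
blob_centroid <- function(image, centre, radius = 26) {
  x0 <- max(0, floor(centre[1] - radius))
  x1 <- min(nrow(image) - 1, ceiling(centre[1] + radius))
  y0 <- max(0, floor(centre[2] - radius))
  y1 <- min(ncol(image) - 1, ceiling(centre[2] + radius))
  xs <- x0:x1; ys <- y0:y1
  win <- image[xs + 1, ys + 1]
  mask <- outer((xs - centre[1])^2, (ys - centre[2])^2, "+") <= radius^2
  wgt <- pmax(win, 0) * mask
  s <- sum(wgt)
  if (s <= 0) stop("no intensity inside centroid window")
  c(sum(wgt * matrix(xs, length(xs), length(ys))) / s,
    sum(wgt * matrix(ys, length(xs), length(ys), byrow = TRUE)) / s)
}

#' Principal-axis angle of an image window by second moments
#'
#' Returns the orientation (degrees, in (-90, 90]) of the dominant
#' eigenvector of the intensity covariance of the window around
#' \code{centre}; comparable to an in-plane rotation angle modulo 180.
#'
#' @inheritParams blob_centroid
#' @return angle in degrees.
#' @export
principal_axis_angle <- function(image, centre, radius = 26) {
  x0 <- max(0, floor(centre[1] - radius))
  x1 <- min(nrow(image) - 1, ceiling(centre[1] + radius))
  y0 <- max(0, floor(centre[2] - radius))
  y1 <- min(ncol(image) - 1, ceiling(centre[2] + radius))
  xs <- x0:x1; ys <- y0:y1
  win <- image[xs + 1, ys + 1]
  mask <- outer((xs - centre[1])^2, (ys - centre[2])^2, "+") <= radius^2
  wgt <- pmax(win, 0) * mask
  s <- sum(wgt)
  gx <- matrix(xs, length(xs), length(ys))
  gy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  mx <- sum(wgt * gx) / s
  my <- sum(wgt * gy) / s
  cxx <- sum(wgt * (gx - mx)^2) / s
  cyy <- sum(wgt * (gy - my)^2) / s
  cxy <- sum(wgt * (gx - mx) * (gy - my)) / s
  0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
}
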