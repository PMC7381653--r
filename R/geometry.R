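# Elementary rotation matrices (degrees, extrinsic / rotate-reference).
# Right-handed, counter-clockwise for positive angles when looking down the
# axis towards the origin.

#' Elementary rotation about the Z axis
#'
#' @param deg angle in degrees (counter-clockwise, right-handed).
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Elementary rotation about the Y axis
#' @inheritParams rot_z
#' @return 3x3 rotation matrix.
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Elementary rotation about the X axis
#' @inheritParams rot_z
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

.assert_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R)))
    stop("not a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance ", tol)
  if (abs(det(R) - 1) > tol * 10)
    stop("matrix determinant is not +1 (improper rotation)")
  invisible(R)
}

#' Convert a ZXZ Euler triplet to a rotation matrix
#'
#' Dynamo subtomogram tables store orientations as (tdrot, tilt, narot) in
#' the extrinsic ZXZ convention: the composed matrix is
#' \code{Rz(narot) \%*\% Rx(tilt) \%*\% Rz(tdrot)}.
#'
#' @param tdrot,tilt,narot angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
zxz_to_matrix <- function(tdrot, tilt, narot) {
  stopifnot(is.finite(tdrot), is.finite(tilt), is.finite(narot))
  rot_z(narot) %*% rot_x(tilt) %*% rot_z(tdrot)
}

#' Convert a ZYZ Euler triplet to a rotation matrix
#'
#' SPA packages (Relion convention) store orientations as (rot, tilt, psi)
#' in the extrinsic ZYZ convention: \code{Rz(psi) \%*\% Ry(tilt) \%*\% Rz(rot)}.
#'
#' @param rot,tilt,psi angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
zyz_to_matrix <- function(rot, tilt, psi) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Decompose a rotation matrix into ZYZ Euler angles
#'
#' Inverts \code{\link{zyz_to_matrix}}. The tilt angle is returned in
#' [0, 180] degrees. At gimbal lock (tilt ~ 0 or ~ 180) the decomposition is
#' degenerate; the convention here sets \code{rot = 0} and folds the whole
#' in-plane rotation into \code{psi}.
#'
#' @param R 3x3 rotation matrix (validated: orthonormal, det +1).
#' @param tol validation tolerance.
#' @return named numeric vector \code{c(rot, tilt, psi)} in degrees.
#' @export
matrix_to_zyz <- function(R, tol = 1e-6) {
  .assert_rotation(R, tol)
  ct <- min(1, max(-1, R[3, 3]))
  tilt <- acos(ct)
  st <- sin(tilt)
  if (st > 1e-9) {
    psi <- atan2(R[2, 3], R[1, 3])
    rot <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {          # tilt ~ 0: R ~ Rz(psi + rot)
    rot <- 0
    psi <- atan2(R[2, 1], R[1, 1])
  } else {                      # tilt ~ 180: R ~ Rz(psi - rot) * Ry(180)
    rot <- 0
    psi <- atan2(-R[2, 1], R[2, 2])
  }
  c(rot = rot * 180 / pi, tilt = tilt * 180 / pi, psi = psi * 180 / pi)
}

#' Decompose a rotation matrix into ZXZ Euler angles
#'
#' Inverts \code{\link{zxz_to_matrix}}; tilt in [0, 180], \code{tdrot = 0}
#' at gimbal lock (in-plane rotation folded into \code{narot}).
#'
#' @inheritParams matrix_to_zyz
#' @return named numeric vector \code{c(tdrot, tilt, narot)} in degrees.
#' @export
matrix_to_zxz <- function(R, tol = 1e-6) {
  .assert_rotation(R, tol)
  ct <- min(1, max(-1, R[3, 3]))
  tilt <- acos(ct)
  st <- sin(tilt)
  if (st > 1e-9) {
    narot <- atan2(R[1, 3], -R[2, 3])
    tdrot <- atan2(R[3, 1], R[3, 2])
  } else if (ct > 0) {          # tilt ~ 0: R ~ Rz(narot + tdrot)
    tdrot <- 0
    narot <- atan2(R[2, 1], R[1, 1])
  } else {                      # tilt ~ 180
    tdrot <- 0
    narot <- atan2(R[2, 1], R[1, 1])
  }
  c(tdrot = tdrot * 180 / pi, tilt = tilt * 180 / pi,
    narot = narot * 180 / pi)
}

# Rotation part of a 2D affine by polar decomposition (closest rotation in
# the Frobenius sense); mirrors (det < 0) are rejected upstream.
.polar_rotation_2d <- function(A) {
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0)
    stop("2D affine contains a mirror (negative determinant); unsupported")
  R
}

#' Projection geometry for one tilt image
#'
#' Bundles everything needed to map tomogram voxels onto one micrograph of
#' the tilt series: the stage tilt (a rotation about the micrograph Y axis,
#' IMOD's rotated-to-vertical tilt-axis convention), the in-plane 2D affine
#' for that image, the tomogram and micrograph centres, and the binning
#' factor (micrograph pixels per tomogram voxel edge).
#'
#' When built from a \code{\link{tilt_alignment}}, the stored affine is the
#' \emph{applied} transform, i.e. the inverse of the .xf record: .xf maps raw
#' micrograph coordinates to aligned-stack coordinates, and the export walks
#' the chain backwards from tomogram-aligned space onto the raw high-dose
#' micrograph.
#'
#' @param align a \code{tilt_alignment} object.
#' @param image index of the tilt image in the alignment (default: the
#'   zero-tilt image).
#' @param invert_xf invert the stored .xf transform (default TRUE; see
#'   Details).
#' @return object of class \code{projection_geometry}.
#' @export
projection_geometry <- function(align, image = zero_tilt_index(align),
                                invert_xf = TRUE) {
  stopifnot(inherits(align, "tilt_alignment"))
  A <- align$xf[[image]]$A
  sh <- align$xf[[image]]$shift
  if (abs(det(A)) < 1e-6) stop("in-plane affine is singular")
  if (invert_xf) {
    Ai <- solve(A)
    sh <- as.numeric(-Ai %*% sh)
    A <- Ai
  }
  g <- list(
    tilt_angle = align$angles[image],
    A = A, shift = sh,
    tomogram_centre = (align$tomogram_size + 1) / 2,   # 1-based voxel centre
    micrograph_centre = (align$image_size - 1) / 2,    # 0-based pixel centre
    binning = align$binning
  )
  if (abs(g$tilt_angle) > 70)
    stop("tilt angle ", g$tilt_angle, " outside supported range [-70, 70]")
  class(g) <- "projection_geometry"
  g
}

#' Compose the full rotation for a 2D-exported particle
#'
#' The orientation of a particle in the high-dose micrograph is the product
#' of (a) the in-plane rotation of the alignment affine (polar-decomposed
#' rotation part, promoted to 3D about Z), (b) the stage tilt about Y, and
#' (c) the subtomogram-averaging pose itself (ZXZ):
#' \deqn{R_{mic} = R_{inplane} R_y(tilt) R_{ZXZ}}
#' At zero tilt with an identity alignment this is the StA rotation
#' unchanged.
#'
#' @param pose one subtomogram pose: list/row with \code{tdrot, tilt, narot}.
#' @param geom a \code{\link{projection_geometry}}.
#' @return 3x3 rotation matrix.
#' @export
compose_pose <- function(pose, geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (det(geom$A) < 0)
    stop("in-plane affine contains a mirror; unsupported")
  R2 <- .polar_rotation_2d(geom$A)
  Rin <- diag(3)
  Rin[1:2, 1:2] <- R2
  Rin %*% rot_y(geom$tilt_angle) %*%
    zxz_to_matrix(pose$tdrot, pose$tilt, pose$narot)
}

#' Map a subtomogram position onto a micrograph
#'
#' Centres the tomogram coordinate, applies the stage tilt rotation about Y,
#' projects orthographically, scales by binning and applies the in-plane
#' affine. The third (beam-direction) component of the tilt-rotated centred
#' coordinate is returned as \code{z_offset} in tomogram voxels; it feeds
#' the per-particle defocus update.
#'
#' @param pose list/row with \code{x, y, z} (1-based tomogram voxels) and
#'   \code{dx, dy, dz} (refinement shifts, voxels).
#' @param geom a \code{\link{projection_geometry}}.
#' @return list with \code{xy} (0-based micrograph pixels, length 2) and
#'   \code{z_offset} (voxels).
#' @export
map_position <- function(pose, geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  p <- c(pose$x + pose$dx, pose$y + pose$dy, pose$z + pose$dz)
  cc <- p - geom$tomogram_centre
  r <- as.numeric(rot_y(geom$tilt_angle) %*% cc)
  q <- r[1:2] * geom$binning
  xy <- as.numeric(geom$A %*% q) + geom$shift + geom$micrograph_centre
  list(xy = xy, z_offset = r[3])
}

#' Export subtomogram poses as 2D single-particle records
#'
#' Implements the StA-to-SPA handover: every in-bounds pose in a Dynamo-style
#' particle table becomes a 2D particle record on the high-dose zero-tilt
#' micrograph, carrying its projected coordinate, its composed orientation
#' re-expressed as ZYZ Euler angles, and a per-particle defocus updated from
#' the particle's Z-height in the tomogram. Out-of-bounds particles are
#' returned in a rejection table with reasons, never silently dropped.
#'
#' @param table particle table (data.frame from
#'   \code{\link{read_particle_table}}).
#' @param align a \code{\link{tilt_alignment}}; must contain a zero-tilt
#'   image.
#' @param defocus_centre defocus (Angstrom, underfocus positive) at the
#'   tomogram centre; recycled to \code{c(u, v)} if scalar.
#' @param ctf a \code{\link{ctf_model}} giving astigmatism angle, pixel size
#'   and optics metadata.
#' @param box_size extraction box size in pixels; particles closer than half
#'   a box to the micrograph edge are rejected.
#' @param halfset integer vector (1/2) of half-set labels, one per table
#'   row; default splits by odd/even tag.
#' @param micrograph_name name recorded in the STAR output.
#' @return list with \code{particles} (data.frame of exported records) and
#'   \code{rejected} (data.frame of tag + reason).
#' @export
export_particles <- function(table, align, defocus_centre, ctf,
                             box_size = 64, halfset = NULL,
                             micrograph_name = "high_dose.mrc") {
  stopifnot(inherits(align, "tilt_alignment"), inherits(ctf, "ctf_model"))
  zi <- zero_tilt_index(align)
  geom <- projection_geometry(align, zi)
  defocus_centre <- rep_len(defocus_centre, 2)
  if (is.null(halfset)) halfset <- ifelse(table$tag %% 2 == 1, 1L, 2L)
  stopifnot(length(halfset) == nrow(table))
  voxel_size <- ctf$pixel_size * align$binning

  n <- nrow(table)
  out <- vector("list", n)
  rej <- list()
  half <- box_size / 2
  for (i in seq_len(n)) {
    pose <- table[i, ]
    m <- map_position(pose, geom)
    zyz <- matrix_to_zyz(compose_pose(pose, geom))
    df <- particle_defocus(
      ctf_update(ctf, defocus_u = defocus_centre[1],
                 defocus_v = defocus_centre[2]),
      m$z_offset, voxel_size)
    inb <- all(m$xy >= half) &&
      all(m$xy <= align$image_size - 1 - half)
    rec <- data.frame(
      tag = pose$tag,
      coord_x = m$xy[1], coord_y = m$xy[2],
      rot = zyz[["rot"]], tilt = zyz[["tilt"]], psi = zyz[["psi"]],
      defocus_u = df[["defocus_u"]], defocus_v = df[["defocus_v"]],
      defocus_angle = ctf$defocus_angle,
      z_offset = m$z_offset,
      halfset = halfset[i],
      micrograph = micrograph_name,
      stringsAsFactors = FALSE)
    if (inb) {
      out[[i]] <- rec
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        tag = pose$tag, coord_x = m$xy[1], coord_y = m$xy[2],
        reason = "out_of_bounds", stringsAsFactors = FALSE)
    }
  }
  particles <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(particles)) particles <- data.frame()
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(tag = integer(), coord_x = numeric(), coord_y = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  list(particles = particles, rejected = rejected)
}
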