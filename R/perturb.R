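# Misalignment injection: add Gaussian noise to the refinement shifts and
# Euler angles of a subtomogram table, emulating degraded alignment quality.

#' Perturb a subtomogram alignment table
#'
#' Adds independent zero-mean Gaussian noise to the three shift components
#' (voxels) and the three ZXZ Euler components (degrees) of every particle.
#' Tags, positions, scores and any extra columns are untouched. The
#' reference misalignment levels are sigma = 1, 3 and 5 (small, moderate,
#' significant), applied to both shifts and angles; the two sigmas can also
#' be set independently.
#'
#' @param table a \code{dynamo_table} data.frame.
#' @param sigma_shift standard deviation of shift noise, voxels (>= 0).
#' @param sigma_angle standard deviation of angle noise, degrees; defaults
#'   to \code{sigma_shift} (the shared-sigma convention).
#' @param seed RNG seed; identical seeds give identical outputs.
#' @return the perturbed table.
#' @export
perturb_table <- function(table, sigma_shift, sigma_angle = sigma_shift,
                          seed = 1) {
  stopifnot(is.data.frame(table), sigma_shift >= 0, sigma_angle >= 0)
  n <- nrow(table)
  set.seed(seed)
  if (sigma_shift > 0) {
    table$dx <- table$dx + stats::rnorm(n, 0, sigma_shift)
    table$dy <- table$dy + stats::rnorm(n, 0, sigma_shift)
    table$dz <- table$dz + stats::rnorm(n, 0, sigma_shift)
  }
  if (sigma_angle > 0) {
    table$tdrot <- table$tdrot + stats::rnorm(n, 0, sigma_angle)
    table$tilt <- table$tilt + stats::rnorm(n, 0, sigma_angle)
    table$narot <- table$narot + stats::rnorm(n, 0, sigma_angle)
  }
  table
}
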