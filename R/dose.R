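# Dose-symmetric tilt-scheme construction and dose-based micrograph
# normalization.
#
# The hybrid acquisition records the untilted image first with a large share
# of the total electron dose, then covers the angular range with a
# dose-symmetric pattern; micrograph grey-level statistics are afterwards
# equalized so that tilt-series alignment tools see comparable images, with
# each image's standard deviation scaled by the square root of its relative
# exposure (shot-noise statistics: variance proportional to 1/dose).

#' Build a (hybrid) dose-symmetric tilt scheme
#'
#' Angles run from \code{min_angle} to \code{max_angle} in steps of
#' \code{step}; acquisition starts at 0 degrees and alternates sides in the
#' dose-symmetric order (0, +s, -s, -2s, +2s, +3s, -3s, -4s, +4s, ...).
#' A conventional scheme splits \code{total_dose} equally over all images; a
#' hybrid scheme gives the zero-tilt image \code{high_dose} electrons and
#' splits the remainder equally over the other angles.
#'
#' @param min_angle,max_angle,step tilt range and increment, degrees; the
#'   step must divide the range and the range must include 0.
#' @param total_dose total electron dose for the series, e-/A^2.
#' @param hybrid logical; redistribute dose onto the zero-tilt image?
#' @param high_dose exposure of the zero-tilt image (e-/A^2), hybrid only;
#'   must be below \code{total_dose}.
#' @param group dose-symmetric group size (images per side before switching;
#'   default 1, strict alternation).
#' @return data.frame of class \code{tilt_scheme} with columns
#'   \code{order} (0-based acquisition index), \code{angle},
#'   \code{exposure} and \code{accumulated_prior} (dose received before the
#'   image was taken), ordered by acquisition.
#' @export
make_scheme <- function(min_angle, max_angle, step, total_dose,
                        hybrid = FALSE, high_dose = NULL, group = 1) {
  stopifnot(step > 0, max_angle > min_angle, total_dose > 0, group >= 1)
  nspan <- (max_angle - min_angle) / step
  if (abs(nspan - round(nspan)) > 1e-9)
    stop("step does not divide the angular range")
  angles <- seq(min_angle, max_angle, by = step)
  if (!any(abs(angles) < 1e-9))
    stop("angular range does not include 0")
  # dose-symmetric acquisition order
  pos <- sort(angles[angles > 1e-9])
  neg <- sort(abs(angles[angles < -1e-9]))
  order_angles <- 0
  ip <- 1; ineg <- 1; side_pos_first <- TRUE
  while (ip <= length(pos) || ineg <= length(neg)) {
    take <- function(v, i) v[seq.int(i, min(i + group - 1, length(v)))]
    if (side_pos_first) {
      if (ip <= length(pos)) {
        t <- take(pos, ip); order_angles <- c(order_angles, t)
        ip <- ip + length(t)
      }
      if (ineg <= length(neg)) {
        t <- take(neg, ineg); order_angles <- c(order_angles, -t)
        ineg <- ineg + length(t)
      }
    } else {
      if (ineg <= length(neg)) {
        t <- take(neg, ineg); order_angles <- c(order_angles, -t)
        ineg <- ineg + length(t)
      }
      if (ip <= length(pos)) {
        t <- take(pos, ip); order_angles <- c(order_angles, t)
        ip <- ip + length(t)
      }
    }
    side_pos_first <- !side_pos_first
  }
  n <- length(order_angles)
  if (hybrid) {
    if (is.null(high_dose)) stop("hybrid scheme requires high_dose")
    if (high_dose >= total_dose)
      stop("high_dose (", high_dose, ") must be below total_dose (",
           total_dose, ")")
    exposure <- rep((total_dose - high_dose) / (n - 1), n)
    exposure[1] <- high_dose
  } else {
    exposure <- rep(total_dose / n, n)
  }
  sch <- data.frame(order = seq_len(n) - 1L, angle = order_angles,
                    exposure = exposure,
                    accumulated_prior = cumsum(c(0, exposure[-n])))
  attr(sch, "total_dose") <- total_dose
  attr(sch, "hybrid") <- hybrid
  class(sch) <- c("tilt_scheme", "data.frame")
  sch
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf("%s tilt scheme: %d images, total dose %.3g e-/A^2\n",
              if (isTRUE(attr(x, "hybrid"))) "hybrid" else "conventional",
              nrow(x), attr(x, "total_dose")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Normalization target for a dose-graded stack
#'
#' All micrographs are brought to a common mean; standard deviations are
#' assigned per exposure via the dose relation
#' \eqn{\sigma_{HD}^2 / \sigma_{LD}^2 = e_{LD} / e_{HD}}: images carrying
#' more electrons have proportionally lower variance after normalization,
#' reflecting their higher intrinsic signal-to-noise.
#'
#' @param target_mean grey-level mean every image is mapped to.
#' @param reference_sigma grey-level standard deviation assigned to an
#'   image at \code{reference_exposure}.
#' @param reference_exposure exposure (e-/A^2) at which
#'   \code{reference_sigma} applies.
#' @return object of class \code{norm_spec}.
#' @export
norm_spec <- function(target_mean = 128, reference_sigma = 11,
                      reference_exposure = 2) {
  stopifnot(reference_sigma > 0, reference_exposure > 0)
  structure(list(target_mean = target_mean,
                 reference_sigma = reference_sigma,
                 reference_exposure = reference_exposure),
            class = "norm_spec")
}

#' Standard deviation assigned to a given exposure
#'
#' Evaluates the dose-based variance relation: an image that received
#' \code{exposure} electrons per square Angstrom is normalized to
#' \code{reference_sigma * sqrt(reference_exposure / exposure)}.
#'
#' @param spec a \code{\link{norm_spec}}.
#' @param exposure e-/A^2, positive.
#' @return grey-level standard deviation.
#' @export
sigma_for_exposure <- function(spec, exposure) {
  stopifnot(inherits(spec, "norm_spec"))
  if (any(exposure <= 0)) stop("exposure must be positive")
  spec$reference_sigma * sqrt(spec$reference_exposure / exposure)
}

#' Normalize a dose-graded micrograph stack
#'
#' Applies a per-image affine map \code{a*x + b} so that each micrograph
#' has mean \code{spec$target_mean} and standard deviation
#' \code{\link{sigma_for_exposure}(spec, exposure)}. Idempotent: a second
#' application is a no-op.
#'
#' @param images list of matrices.
#' @param exposures numeric vector of exposures, one per image (e-/A^2).
#' @param spec a \code{\link{norm_spec}}.
#' @return list of normalized matrices.
#' @export
normalize_stack <- function(images, exposures, spec) {
  stopifnot(inherits(spec, "norm_spec"),
            length(images) == length(exposures))
  lapply(seq_along(images), function(i) {
    x <- images[[i]]
    s <- stats::sd(as.numeric(x))
    if (!is.finite(s) || s == 0)
      stop("image ", i, " has zero variance; cannot normalize")
    target_sd <- sigma_for_exposure(spec, exposures[i])
    a <- target_sd / s
    y <- a * (x - mean(x)) + spec$target_mean
    y
  })
}
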