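# Contrast transfer function model, per-particle defocus from tomogram
# Z-height, restricted-frequency defocus-estimation precision experiment,
# and 2D CTF correction (phase flipping vs Wiener filtering).

#' Construct a CTF model
#'
#' @param defocus_u,defocus_v defocus along the astigmatism axes, Angstrom;
#'   underfocus positive.
#' @param defocus_angle astigmatism azimuth, degrees.
#' @param voltage acceleration voltage, kV.
#' @param cs spherical aberration, mm.
#' @param amplitude_contrast amplitude-contrast fraction in [0, 1].
#' @param pixel_size detector pixel size, Angstrom.
#' @param phase_shift additional phase shift, radians (phase plate; 0).
#' @return object of class \code{ctf_model}.
#' @export
ctf_model <- function(defocus_u = 40000, defocus_v = defocus_u,
                      defocus_angle = 0, voltage = 300, cs = 2.7,
                      amplitude_contrast = 0.07, pixel_size = 1.7,
                      phase_shift = 0) {
  stopifnot(voltage > 0, pixel_size > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 defocus_angle = defocus_angle, voltage = voltage,
                 cs = cs, amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size, phase_shift = phase_shift),
            class = "ctf_model")
}

#' @export
print.ctf_model <- function(x, ...) {
  cat(sprintf(
    "ctf_model: defocus %.0f/%.0f A @ %.1f deg, %g kV, Cs %g mm, AC %g, %g A/px\n",
    x$defocus_u, x$defocus_v, x$defocus_angle, x$voltage, x$cs,
    x$amplitude_contrast, x$pixel_size))
  invisible(x)
}

# clone with replaced fields
ctf_update <- function(ctf, ...) {
  upd <- list(...)
  ctf[names(upd)] <- upd
  ctf
}

#' Relativistic electron wavelength
#' @param voltage acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage) {
  v <- voltage * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Update per-particle defocus from tomogram Z-height
#'
#' The defocus at the tomogram centre is known from whole-micrograph CTF
#' estimation; each particle's defocus differs by its height along the beam.
#' Sign convention: positive \code{z_offset} means farther from the electron
#' source, i.e. larger defocus (more underfocus). The convention is isolated
#' in the \code{sign} argument; the astigmatism angle is unchanged.
#'
#' @param ctf a \code{\link{ctf_model}} holding the centre defocus.
#' @param z_offset particle height relative to the tomogram centre, voxels.
#' @param voxel_size tomogram voxel size, Angstrom.
#' @param sign +1 (default) or -1, the Z-to-defocus sign convention.
#' @return named numeric \code{c(defocus_u, defocus_v)} in Angstrom.
#' @export
particle_defocus <- function(ctf, z_offset, voxel_size, sign = 1) {
  stopifnot(inherits(ctf, "ctf_model"), voxel_size > 0, abs(sign) == 1)
  dz <- sign * z_offset * voxel_size
  c(defocus_u = ctf$defocus_u + dz, defocus_v = ctf$defocus_v + dz)
}

#' Evaluate the contrast transfer function
#'
#' Standard weak-phase/weak-amplitude CTF:
#' \deqn{CTF(q) = -\sqrt{1 - A^2}\,\sin\chi(q) - A\,\cos\chi(q)}
#' with aberration phase
#' \eqn{\chi(q) = \pi\lambda z q^2 - (\pi/2) C_s \lambda^3 q^4 + \phi}.
#' At \eqn{q = 0} the value is \eqn{-A} (pure amplitude term). With
#' astigmatism, the effective defocus at azimuth \eqn{\theta} is
#' \eqn{z(\theta) = (z_u + z_v)/2 + (z_u - z_v)/2\,\cos 2(\theta - \theta_a)}.
#'
#' @param ctf a \code{\link{ctf_model}}.
#' @param freq spatial frequency, 1/Angstrom (vector).
#' @param azimuth azimuth of the frequency vector, radians (scalar or
#'   vector matching \code{freq}); only matters for astigmatic models.
#' @return CTF amplitude(s) in [-1, 1].
#' @export
ctf_eval <- function(ctf, freq, azimuth = 0) {
  stopifnot(inherits(ctf, "ctf_model"), all(freq >= 0))
  lambda <- electron_wavelength(ctf$voltage)
  cs_a <- ctf$cs * 1e7                     # mm -> Angstrom
  zmean <- (ctf$defocus_u + ctf$defocus_v) / 2
  zdiff <- (ctf$defocus_u - ctf$defocus_v) / 2
  za <- ctf$defocus_angle * pi / 180
  z <- zmean + zdiff * cos(2 * (azimuth - za))
  chi <- pi * lambda * z * freq^2 -
    (pi / 2) * cs_a * lambda^3 * freq^4 + ctf$phase_shift
  A <- ctf$amplitude_contrast
  -sqrt(1 - A^2) * sin(chi) - A * cos(chi)
}

# 2D CTF over the FFT frequency grid of an n x n image.
ctf_eval_2d <- function(ctf, n) {
  fx <- ((0:(n - 1) + n %/% 2) %% n - n %/% 2) / (n * ctf$pixel_size)
  qx <- matrix(fx, n, n)
  qy <- matrix(fx, n, n, byrow = TRUE)
  q <- sqrt(qx^2 + qy^2)
  th <- atan2(qy, qx)
  matrix(ctf_eval(ctf, as.numeric(q), as.numeric(th)), n, n)
}

#' Simulate a micrograph power spectrum
#'
#' Rotationally symmetric Thon-ring pattern \eqn{|CTF|^2} under a Gaussian
#' envelope, plus dose-dependent Gaussian noise: the noise standard
#' deviation scales as \eqn{1/\sqrt{dose}}, mirroring shot-noise statistics
#' (a reference dose of 2 e-/A^2 maps to \code{noise_ref}).
#'
#' @param ctf a \code{\link{ctf_model}}.
#' @param n spectrum side length, pixels.
#' @param dose exposure, e-/A^2.
#' @param noise_ref noise sigma at the 2 e-/A^2 reference dose (0 = clean).
#' @param envelope_b Gaussian envelope B-factor, Angstrom^2.
#' @return n x n matrix (power spectrum, DC at the corner convention of the
#'   FFT grid).
#' @export
simulate_spectrum <- function(ctf, n = 256, dose = 15, noise_ref = 0.5,
                              envelope_b = 60) {
  c2 <- ctf_eval_2d(ctf, n)^2
  fx <- ((0:(n - 1) + n %/% 2) %% n - n %/% 2) / (n * ctf$pixel_size)
  q2 <- outer(fx^2, fx^2, "+")
  env <- exp(-envelope_b * q2 / 2)
  s <- c2 * env
  if (noise_ref > 0) {
    sigma <- noise_ref * sqrt(2 / dose)
    s <- s + matrix(stats::rnorm(n * n, 0, sigma), n, n)
  }
  s
}

# Rotationally average a 2D FFT-grid spectrum into radial bins. Returns
# bin-mean frequency and power plus the bin edges, so a model can be
# averaged over the same bins.
radial_average <- function(spec, pixel_size) {
  n <- nrow(spec)
  fx <- ((0:(n - 1) + n %/% 2) %% n - n %/% 2) / (n * pixel_size)
  q <- sqrt(outer(fx^2, fx^2, "+"))
  nyq <- 1 / (2 * pixel_size)
  nb <- n %/% 2
  step <- nyq / (nb - 1)
  bin <- pmin(nb, 1L + as.integer(floor(q / step + 0.5)))
  keep <- q <= nyq
  prof <- tapply(spec[keep], bin[keep], mean)
  qs <- tapply(q[keep], bin[keep], mean)
  idx <- as.integer(names(prof))
  list(q = as.numeric(qs), p = as.numeric(prof),
       lo = (idx - 1.5) * step, hi = (idx - 0.5) * step)
}

# Average |CTF|^2 over radial bins with area weighting (annulus density
# ~ q), mirroring how the data spectrum is averaged; point evaluation at
# the bin centre would bias the fit where rings oscillate faster than the
# bin width.
.model_profile <- function(ctf, lo, hi, nsub = 9) {
  u <- (seq_len(nsub) - 0.5) / nsub
  l0 <- pmax(0, lo)
  qq <- outer(u, hi - l0) + rep(l0, each = nsub)   # nsub x nbins
  w <- pmax(qq, 1e-12)
  m <- matrix(ctf_eval(ctf, as.numeric(qq))^2, nrow = nsub)
  colSums(m * w) / colSums(w)
}

#' Estimate defocus from a power spectrum
#'
#' Rotationally averages the spectrum, removes a smooth background (ramp
#' plus Gaussian-smoothed residual) and finds, within +/- 20 percent of the
#' initial guess, the defocus whose squared CTF best correlates with the
#' Thon-ring profile inside a resolution band. Astigmatism is fixed at the
#' initial guess (1D fitting).
#'
#' @param spectrum square matrix (power spectrum on the FFT grid) as
#'   produced by \code{\link{simulate_spectrum}}.
#' @param ctf0 initial-guess \code{\link{ctf_model}} (supplies optics and
#'   the search centre defocus).
#' @param res_range c(low, high) resolution band in Angstrom, low > high;
#'   only frequencies between 1/low and 1/high are fitted.
#' @return list with \code{defocus} (Angstrom) and \code{correlation}.
#' @export
estimate_defocus <- function(spectrum, ctf0, res_range) {
  stopifnot(inherits(ctf0, "ctf_model"), length(res_range) == 2,
            res_range[1] > res_range[2])
  ra <- radial_average(spectrum, ctf0$pixel_size)
  qlo <- 1 / res_range[1]; qhi <- 1 / res_range[2]
  sel <- ra$q >= qlo & ra$q <= qhi
  if (sum(sel) < 8)
    stop("empty or near-empty fitting band ", res_range[1], "-",
         res_range[2], " A")
  q <- ra$q[sel]
  p <- ra$p[sel]
  lo <- ra$lo[sel]; hi <- ra$hi[sel]
  # identical smooth-background removal for data and model keeps the
  # correlation peak unbiased: both sides are high-passed the same way.
  # Polynomial background as a precomputed QR projection (cheap inside the
  # search loop); its degree scales with the number of Thon rings in the
  # band so a narrow two-ring band is not flattened by a quartic.
  z0 <- (ctf0$defocus_u + ctf0$defocus_v) / 2
  lambda <- electron_wavelength(ctf0$voltage)
  chi_q <- function(qq) pi * lambda * z0 * qq^2 -
    (pi / 2) * ctf0$cs * 1e7 * lambda^3 * qq^4
  n_rings <- abs(chi_q(qhi) - chi_q(qlo)) / pi
  degree <- min(4, max(1, floor(n_rings / 2)))
  Qr <- qr(cbind(1, stats::poly(q, degree = degree)))
  hp <- function(y) qr.resid(Qr, y)
  sig <- hp(p)
  if (stats::sd(sig) < 1e-12)
    stop("no contrast in the fitting band")
  obj <- function(z) {
    m <- hp(.model_profile(ctf_update(ctf0, defocus_u = z,
                                      defocus_v = z), lo, hi))
    if (stats::sd(m) < 1e-12) return(0)
    stats::cor(sig, m)
  }
  # The correlation landscape oscillates (ring-shift aliasing), so a coarse
  # grid locates the global basin before a local refine; the grid step is
  # well below half a ring period in defocus at Nyquist.
  grid <- seq(0.8 * z0, 1.2 * z0, length.out = 201)
  vals <- vapply(grid, obj, numeric(1))
  k <- which.max(vals)
  opt <- stats::optimize(obj, lower = grid[max(1, k - 1)],
                         upper = grid[min(length(grid), k + 1)],
                         maximum = TRUE, tol = 0.5)
  list(defocus = opt$maximum, correlation = opt$objective)
}

#' Defocus-estimation precision versus frequency cutoff
#'
#' Monte-Carlo version of the restricted-frequency experiment: simulate
#' \code{n} noisy power spectra at random true defocus values, estimate the
#' defocus of each once with the full frequency band and once per
#' resolution cutoff, and report the root-mean-square deviation of each
#' restricted estimate from the full-band estimate. Excluding high
#' frequencies degrades precision; admitting them recovers it.
#'
#' @param n number of simulated micrograph spectra.
#' @param true_defocus_range c(min, max) true defocus, Angstrom.
#' @param dose exposure of the simulated image, e-/A^2 (noise scales as
#'   \eqn{1/\sqrt{dose}}).
#' @param cutoffs resolution cutoffs in Angstrom (high-frequency limits to
#'   which fitting is restricted), e.g. c(20, 15, 10, 5).
#' @param seed RNG seed (deterministic results).
#' @param ctf0 optics template; defocus fields are overwritten per image.
#' @param n_pix simulated spectrum side length.
#' @param low_res low-resolution end of every fitting band, Angstrom.
#' @param noise_ref noise sigma at the 2 e-/A^2 reference dose.
#' @return data.frame of class \code{precision_result}: \code{cutoff},
#'   \code{rms_defocus_error} (Angstrom), \code{n}.
#' @export
precision_experiment <- function(n = 47, true_defocus_range = c(35000, 45000),
                                 dose = 16, cutoffs = c(20, 15, 10, 5),
                                 seed = 1, ctf0 = ctf_model(),
                                 n_pix = 256, low_res = 50,
                                 noise_ref = 0.5) {
  stopifnot(n >= 2, all(cutoffs > 2 * ctf0$pixel_size))
  set.seed(seed)
  full_hi <- 2 * ctf0$pixel_size * 1.02    # just shy of Nyquist
  true_z <- stats::runif(n, true_defocus_range[1], true_defocus_range[2])
  err <- matrix(NA_real_, n, length(cutoffs))
  for (i in seq_len(n)) {
    ctf_i <- ctf_update(ctf0, defocus_u = true_z[i], defocus_v = true_z[i])
    sp <- simulate_spectrum(ctf_i, n = n_pix, dose = dose,
                            noise_ref = noise_ref)
    guess <- ctf_update(ctf0, defocus_u = true_z[i] * 1.02,
                        defocus_v = true_z[i] * 1.02)
    full <- estimate_defocus(sp, guess, c(low_res, full_hi))$defocus
    for (j in seq_along(cutoffs)) {
      zj <- estimate_defocus(sp, guess, c(low_res, cutoffs[j]))$defocus
      err[i, j] <- zj - full
    }
  }
  out <- data.frame(cutoff = cutoffs,
                    rms_defocus_error = sqrt(colMeans(err^2)),
                    n = n)
  class(out) <- c("precision_result", "data.frame")
  out
}

#' @export
print.precision_result <- function(x, ...) {
  cat("defocus-estimation precision vs frequency cutoff (n =", x$n[1],
      "images)\n")
  print.data.frame(
    data.frame(`cutoff_A` = x$cutoff,
               `rms_defocus_error_A` = round(x$rms_defocus_error, 1)),
    row.names = FALSE)
  invisible(x)
}

#' CTF-correct a 2D image
#'
#' Phase flipping multiplies every Fourier component by the sign of the CTF
#' (restoring phases, leaving the oscillating amplitude modulation); the
#' Wiener filter multiplies by \eqn{CTF/(CTF^2 + 1/SNR)}, additionally
#' reweighting amplitudes and damping the zero crossings. DC-term policy:
#' both filters treat q = 0 like any other frequency, so with amplitude
#' contrast > 0 the DC sign is negative and the corrected image's global
#' contrast is inverted relative to the raw (defocused) image — the usual
#' dark-on-bright to density-positive flip.
#'
#' @param image square numeric matrix.
#' @param ctf a \code{\link{ctf_model}}.
#' @param mode "phase_flip" or "wiener".
#' @param snr signal-to-noise parameter for the Wiener filter (> 0).
#' @return corrected image (real matrix, same size).
#' @export
correct_2d <- function(image, ctf, mode = c("phase_flip", "wiener"),
                       snr = 1) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  H <- ctf_eval_2d(ctf, n)
  FT <- stats::fft(image)
  G <- switch(mode,
    phase_flip = {
      s <- sign(H); s[s == 0] <- 1
      FT * s
    },
    wiener = {
      stopifnot(snr > 0)
      FT * H / (H^2 + 1 / snr)
    })
  Re(stats::fft(G, inverse = TRUE)) / (n * n)
}

#' Apply a CTF to a 2D image (forward model)
#'
#' Multiplies the image's Fourier transform by the CTF; used to degrade
#' phantoms when validating correction filters.
#'
#' @inheritParams correct_2d
#' @return degraded image (real matrix).
#' @export
apply_ctf <- function(image, ctf) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  H <- ctf_eval_2d(ctf, n)
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / (n * n)
}
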