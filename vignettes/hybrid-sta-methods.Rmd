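---
title: "Hybrid subtomogram averaging: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid subtomogram averaging: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hstax)
```

`hstax` implements the computational handover between subtomogram
averaging (StA) and single-particle analysis (SPA) in a hybrid
cryo-electron-tomography workflow: a dose-symmetric tilt series whose
untilted image is recorded first with a large share of the total electron
dose, conventional StA on the reconstructed tomogram, then re-extraction
of every particle in 2D from that high-dose micrograph with its pose and
defocus translated into SPA metadata. This vignette documents the models,
the coordinate and angle conventions, the numerical choices and what the
bundled synthetic validation does and does not demonstrate.

## Dose model

A tilt scheme over $[\theta_{\min}, \theta_{\max}]$ with step $s$ is
acquired dose-symmetrically: $0, +s, -s, -2s, +2s, +3s, -3s, \dots$, so
the low-tilt images that dominate the reconstruction carry the least
accumulated damage. `make_scheme()` supports strict alternation (group
size 1, the default) and larger per-side groups. In the hybrid variant the
order-0 image is the zero-tilt exposure $e_{HD}$ and the remaining $N-1$
angles share $e_{tot} - e_{HD}$ equally. The reference acquisition used
throughout the package is $-60..60^\circ$, $3^\circ$ step,
$e_{tot} = 95$ e⁻/Å² with $e_{HD} = 15$ e⁻/Å², i.e. 40 low-dose
projections at 2 e⁻/Å².

Micrographs of different exposures are normalized to a common mean
(default 128) with exposure-dependent standard deviations. Under
shot-noise statistics the variance of a micrograph scales inversely with
its dose, hence

$$\frac{\sigma_{HD}^2}{\sigma_{LD}^2} = \frac{e_{LD}}{e_{HD}},$$

implemented as $\sigma(e) = \sigma_{ref}\sqrt{e_{ref}/e}$. With
$\sigma_{ref} = 11$ at 2 e⁻/Å², a 15 e⁻/Å² image receives
$\sigma = 11\sqrt{2/15} \approx 4.02$, a factor
$\sqrt{15/2} \approx 2.7$ lower. `normalize_stack()` applies a per-image
affine map only (no histogram matching), computed in double precision; it
is idempotent, and downstream tools must not rescale the stack afterwards
or the dose weighting is lost.

## Geometry and conventions

Because three ecosystems meet here (IMOD alignment, Dynamo tables, STAR
metadata), every convention is fixed explicitly and validated by the
synthetic scenario rather than assumed:

* **Euler conventions.** Extrinsic (rotate-reference) products
  throughout. Dynamo poses: $R = R_z(narot)\,R_x(tilt)\,R_z(tdrot)$ (ZXZ).
  SPA output: $R = R_z(psi)\,R_y(tilt)\,R_z(rot)$ (ZYZ), tilt in
  $[0, 180]$. At gimbal lock ($\sin tilt \approx 0$) the first angle is
  set to 0 and the whole in-plane rotation folds into the last.
* **Composed orientation.**
  $R_{mic} = R_{inplane}\,R_y(\theta_{stage})\,R_{ZXZ}$, where
  $R_{inplane}$ is the rotation part of the image's 2D affine (polar
  decomposition; mirrors are rejected) promoted to a rotation about Z,
  and the stage tilt axis is the micrograph Y axis after the `.xf`
  rotation — IMOD's convention of rotating the tilt axis to vertical.
  Anisotropic-magnification residuals in the affine are deliberately
  ignored.
* **Transform direction.** An `.xf` record maps raw-micrograph
  coordinates into the aligned stack. The export walks backwards from
  tomogram space onto the raw high-dose micrograph, so
  `projection_geometry()` inverts the record. Getting this direction
  wrong is the classic failure mode; it is pinned by the end-to-end
  marker test, not by documentation alone.
* **Coordinates.** Dynamo positions are 1-based voxel-centre
  coordinates; STAR coordinates are 0-based pixel-centre. The conversion
  happens exactly once, inside `map_position()`: centred tomogram
  coordinates are tilt-rotated, orthographically projected, scaled by the
  binning factor (micrograph pixels per tomogram voxel), then pushed
  through the in-plane affine. The third component of the tilt-rotated
  vector is the particle's Z-offset in voxels.
* **Shifts.** Table shifts are interpreted in the tomogram frame and
  added to positions before projection.
* **Defocus sign.** Positive Z-offset means farther from the electron
  source, hence larger defocus (more underfocus):
  $z_{u,v}(p) = z_{u,v} + z_{offset}\cdot\text{voxel size}$. The
  convention is isolated in one `sign` argument of `particle_defocus()`
  and the synthetic scenario encodes the same convention, so the tests
  are self-consistent whichever sign a facility uses.
* **Half-sets.** No Dynamo table column reliably encodes half-set
  membership, so it is an explicit argument of `export_particles()`,
  defaulting to an odd/even split by particle tag (mirroring the
  even/odd split used for membrane-protein data sets).

Bounds handling is flag-and-report: a particle projecting closer than
half a box to the micrograph edge goes into a rejection table with a
reason, never silently dropped, so particle counts remain auditable
across the pipeline.

## CTF model and the precision experiment

The weak-phase/weak-amplitude transfer function is

$$\mathrm{CTF}(q) = -\sqrt{1 - A^2}\,\sin\chi(q) - A\,\cos\chi(q), \qquad
\chi(q) = \pi\lambda z q^2 - \tfrac{\pi}{2} C_s \lambda^3 q^4 + \phi,$$

with astigmatism entering through
$z(\theta) = \bar z + \Delta z \cos 2(\theta - \theta_a)$. Defaults match
the acquisition this package models: 300 kV, $C_s = 2.7$ mm, amplitude
contrast 0.07, 1.7 Å/px, defocus 3.5–4.5 μm.

`estimate_defocus()` fits the rotationally averaged power spectrum:
background is removed by projecting out a low-order polynomial in $q$,
and the defocus maximizing the correlation between the residual and the
bin-averaged model $|\mathrm{CTF}|^2$ is located by a coarse grid
(201 points over ±20 % of the initial guess, well below half a ring
period in defocus) followed by a local refine (tolerance 0.5 Å). Two
numerical choices matter and were validated on noise-free simulations:

* the model is averaged over each radial bin exactly as the data are
  (area-weighted sub-sampling), because rings oscillate faster than the
  bin width near Nyquist and point evaluation biases the fit;
* the background polynomial degree scales with the number of Thon rings
  in the fitted band ($\min(4, \lfloor n_{rings}/2\rfloor$, at least 1),
  so a narrow two-ring band is not flattened by a quartic.

Astigmatism is held at the initial guess (1D fitting only) — sufficient
for the property-level claims made here, and deliberately far short of a
Ctffind/Gctf reimplementation.

`precision_experiment()` reproduces the restricted-frequency analysis as
a Monte-Carlo simulation: $n$ spectra at true defocus uniform in a range,
dose-dependent Gaussian noise (σ ∝ $1/\sqrt{\text{dose}}$, anchored at
2 e⁻/Å²), a Gaussian envelope ($B = 60$ Å², a mid-range experimental
value), estimated once with the full band (50 Å to just under Nyquist)
and once per cutoff (20, 15, 10, 5 Å); it reports the RMS deviation of
each restricted estimate from the full-band estimate. The expected — and
tested — behaviour is monotone: admitting higher frequencies never
degrades precision, and raising the dose never degrades any cutoff
(asserted with a 1 Å slack for the optimizer's resolution).

### 2D correction

`correct_2d()` implements both correction modes discussed for
2D-extracted particles: phase flipping multiplies Fourier terms by
$\mathrm{sign}(\mathrm{CTF})$; the Wiener filter by
$\mathrm{CTF}/(\mathrm{CTF}^2 + 1/\mathrm{SNR})$. Both treat the DC term
like any other frequency (with amplitude contrast > 0 its sign is
negative, giving the usual global contrast flip). On CTF-degraded disc
phantoms the Wiener restoration has lower RMSE than phase flipping across
the tested defocus range — the "halo" artefact of flip-only correction is
exactly what the hybrid workflow avoids by refining in SPA software.

## Misalignment injection

`perturb_table()` adds zero-mean Gaussian noise to the three shift
components (voxels) and the three Euler components (degrees),
additively and per component — the literal protocol, rather than random
rotation axes. The reference levels σ = 1, 3, 5 use one value for both
units, mirroring the original experiment; independent sigmas are
available. Resolution recovery after perturbation requires the real data
and cluster-scale refinement and is out of scope; the desk-scale proxy
asserted here is that the mean extraction-centroid error on the synthetic
scenario increases strictly across σ ∈ {1, 3, 5}.

## The synthetic scenario

`simulate_scenario()` is the single source of truth for convention
validation. It builds the hybrid scheme, an alignment whose zero-tilt
affine is a known rotation + shift (stored in `.xf` as the inverse, since
`.xf` maps raw → aligned), uniformly random in-bounds positions
(projected min-separation enforced by rejection sampling) and uniformly
random orientations via unit quaternions (no Euler-space bias). Each
particle is rendered on the zero-tilt micrograph as an asymmetric
tri-lobe marker: three Gaussian lobes with zero centre of mass, zero
covariance cross-term and equal masses but different widths, so the
rendered intensity has its centroid exactly at the particle position —
for any 3D orientation — and, for tilt-free poses, its principal axis
exactly along the in-plane angle. The renderer re-derives the
tomogram-to-micrograph chain with explicit inline arithmetic instead of
calling the geometry module, making it an independent oracle.

Two variants exist because a projected 3D object's principal axis is not
any single Euler angle in general: `orientations = "uniform"` (position
and centroid checks, valid for any pose) and `orientations = "inplane"`
(tilt-free poses, where the exported $psi$ must match the image's
principal axis; the test tolerance is 2°, the observed agreement is
milli-degrees). Typical validation sizes are 100 particles on a 1536²
micrograph (sub-0.5-pixel recovery of all markers) and 20–100 particles
for orientation checks; the phantom generation is deterministic and
bitwise reproducible under a seed.

What the phantom does *not* emulate: CTF modulation of the rendered
image, structured background (membranes, gold fiducials), overlapping
particles, tilt-series rendering away from 0°, or beam-induced motion.
Passing tests therefore demonstrate that the bookkeeping and geometry are
exact, not that the workflow's resolution claims hold on real data —
those require the deposited raw data sets and external refinement
engines, and are deliberately outside this package.

## Degenerate inputs and tie-breaks

* Zero-tilt identification requires exactly one image with
  $|\theta| < 0.5^\circ$; none or several is an error.
* Gimbal lock: first Euler angle set to 0 (both conventions).
* Mirror affines (negative determinant) are rejected in pose
  composition.
* Constant images cannot be normalized (zero variance is an error);
  constant extraction-box backgrounds are flagged instead of divided by.
* `estimate_defocus()` refuses bands with fewer than 8 radial bins or no
  contrast after background removal.
* Scenario generation fails after 1000 placement attempts per particle
  rather than degrading separation guarantees.

## Problem sizes

The bundled validation runs at desk scale by design: 256² simulated
spectra, 47–50 images per precision experiment, 100-particle phantoms,
10⁴-row tables for distributional checks. These sizes were chosen so
each property is measured with comfortable statistical margin while the
whole suite stays interactive; all of them are arguments, not constants,
and scale up unchanged.
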