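# hstax

Computational core of the **hybrid subtomogram-averaging (hStA)** workflow
for cryo-electron tomography, in R.

## The problem

Subtomogram averaging (StA) determines macromolecular structures in their
native context, but its resolution is limited by the low electron dose
available per tilt image, imprecise defocus estimation, and beam-induced
sample motion accumulated over a tilt series. The hybrid workflow
redistributes the electron dose: the untilted image of a dose-symmetric
tilt series is recorded first with a large share of the total dose (e.g.
15 e⁻/Å² of a 95 e⁻/Å² series, the remaining 40 projections receiving
2 e⁻/Å² each). Conventional StA on the reconstructed tomogram supplies
approximate particle poses; the particles are then re-extracted in 2D from
the high-dose zero-tilt micrograph and handed to single-particle-analysis
(SPA) software for local refinement, where better CTF estimation, Wiener
filtering and per-particle defocus handling apply.

`hstax` implements everything computational in that handover:

- **Tilt schemes** — dose-symmetric acquisition order
  (0, +s, −s, −2s, +2s, …) with per-image exposure and accumulated-dose
  bookkeeping, conventional or hybrid.
- **Dose-based normalization** — micrographs are scaled to a common mean;
  standard deviations follow the shot-noise relation
  σ²\_HD / σ²\_LD = e⁻\_LD / e⁻\_HD, so a 15 e⁻/Å² image normalized
  against 2 e⁻/Å² references at σ = 11 receives σ ≈ 4
  (σ\_HD = 0.37 × σ\_LD).
- **Pose export** — each Dynamo-style subtomogram pose (ZXZ Euler triplet
  tdrot/tilt/narot, position, shifts) is mapped onto the high-dose
  micrograph through the IMOD alignment (.tlt/.xf):
  R\_mic = R\_inplane · R\_y(tilt) · R\_ZXZ, re-expressed as ZYZ
  (rot/tilt/psi) angles in a Relion-dialect STAR file, with per-particle
  defocus updated from the particle's Z-height,
  defocus(z) = defocus₀ + z · voxel size.
- **CTF machinery** — CTF evaluation, Thon-ring defocus estimation with a
  restricted frequency band, a Monte-Carlo precision-vs-cutoff experiment,
  and 2D correction by phase flipping or Wiener filtering.
- **Extraction** — 2D particle boxes from the micrograph with sub-pixel
  origins, background-annulus normalization, contrast inversion.
- **Misalignment injection** — Gaussian perturbation of table shifts and
  angles (σ = 1/3/5 for small/moderate/significant misalignment).
- **Synthetic scenarios** — a phantom generator (tilt scheme, alignment
  files, particle table, rendered high-dose micrograph with asymmetric
  tri-lobe markers) whose exact ground truth validates the whole chain
  end to end.

File formats: IMOD `.tlt`/`.xf`, Dynamo-style `.tbl`, STAR
(optics + particles blocks), MRC2014.

## Worked example

```r
library(hstax)

# hybrid tilt scheme: -60..60 deg, 3-deg step, 95 e-/A^2 total,
# 15 e-/A^2 on the zero-tilt image
sch <- make_scheme(-60, 60, 3, total_dose = 95, hybrid = TRUE, high_dose = 15)
head(as.data.frame(sch), 5)
#>   order angle exposure accumulated_prior
#> 1     0     0       15                 0
#> 2     1     3        2                15
#> 3     2    -3        2                17
#> 4     3    -6        2                19
#> 5     4     6        2                21

# normalization sigma for the high-dose image
spec <- norm_spec(target_mean = 128, reference_sigma = 11, reference_exposure = 2)
round(sigma_for_exposure(spec, 15), 2)
#> [1] 4.02

# synthetic scenario -> export to SPA metadata
sc  <- simulate_scenario(n_particles = 50, seed = 1)
ctf <- ctf_model(defocus_u = 40000, pixel_size = 1.7)
res <- export_particles(sc$table, sc$align, defocus_centre = 40000,
                        ctf = ctf, box_size = 64)
head(res$particles[, c("tag", "coord_x", "coord_y", "rot", "tilt", "psi",
                       "defocus_u", "halfset")], 3)
#>   tag coord_x coord_y       rot     tilt       psi defocus_u halfset
#> 1   1 286.857 388.995   60.4704 143.0635 -160.9353   40024.1       1
#> 2   2 902.563 225.711 -123.0138  49.3899   92.3409   40139.2       2
#> 3   3 937.499 665.544  179.5365 114.3893 -121.5487   40044.0       1

write_star(res$particles, ctf, "particles.star")
```

The coordinates are 0-based pixels in the high-dose micrograph, the Euler
angles are extrinsic ZYZ in degrees, `defocus_u/v` carry the per-particle
Z-height correction in Å, and `halfset` records the independent half-set
split used for Fourier-shell-correlation validation downstream.

The same steps are scriptable from a shell:

```sh
hstax scheme --range -60 60 --step 3 --total-dose 95 --hybrid --high-dose 15
hstax simulate --n 100 --seed 1 --out fixture/
hstax export --tlt fixture/series.tlt --xf fixture/series.xf \
      --tbl fixture/particles.tbl --image-size 1024 1024 \
      --tomogram-size 480 480 120 --binning 2 --defocus 40000 \
      --pixel-size 1.7 --out particles.star
hstax ctf-precision --n 47 --dose 16 --cutoffs 20,15,10,5 --seed 1
```

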