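# saxsbeam

Beam orientation optimization for small-angle X-ray scattering (SAXS) from
deep targets embedded in large attenuating objects.

## What it is for

SAXS can detect nanoscale structure — e.g. the 4.7 Å cross-β sheet spacing of
amyloid fibrils, at scattering vector `q = 2π/d ≈ 13.4 nm⁻¹` — but a target
buried deep in a large object, such as an amyloid-rich lobe inside a human
head, is only reachable along beam paths that attenuate the signal and smear
the recorded `q`. `saxsbeam` is for medical-physics users planning such
acquisitions: it predicts the scattering profile of a deep target along any
candidate pencil-beam path and ranks the paths by signal conspicuity per
unit dose.

The forward model combines:

* **scattering geometry** — `q = 4π sin θ / λ` (with `2θ` the scattering
  angle) and the geometric spread of recorded `q` across a target of radius
  `r_t` at mean target-to-detector distance `L0`:
  `Δq/q = 2 − 2/(sin θ √(((L0+r_t)/(L0 tan θ))² + 1))`;
* **attenuated scattering intensity** —
  `I/I0 = σ e^(−μl) ∫ρ_t(x)dx`, Beer–Lambert attenuation along the beam's
  chord through the object times the scatterer line density;
* **detector blur** — convolution with a unit-area triangular kernel of base
  width 0.35 × the `q` spread.

Each candidate path is summarized by its peak intensity `I_p`, total
intensity `I_t` (area under the profile) and HWHM spread `Δq`, and scored
with the figure of merit

```
Ω = I_p · I_t / (l · Δq)
```

where the path length `l` stands in for radiation dose. Paths can come from
analytic scenes (spherical/elliptical targets in spherical objects) or from
segmented 2D raster masks (PGM/PNG/CSV labels: background, object, target,
excluded), and a synthetic phantom generator provides ground-truth masks.

## Worked example

A 2 cm spherical target centered in a 10 cm-radius head, 60 keV beam,
detector at 20 cm:

```r
library(saxsbeam)

scene <- scatter_scene(
  target = spherical_target(r_t = 2),
  beam   = beam_geometry(L0 = 20, energy_keV = 60),
  medium = default_medium(),           # mu = 0.30 cm^-1, rho_t = 5.5e5 cm^-3, sigma = 5e-23 cm^2
  object = spherical_object(R_o = 10))

res <- simulate_profile(scene)
res$summary
#>         I_p       I_t delta_q
#> 1 1.019e-19 2.727e-19   1.338
```

The smeared profile peaks at `I_p ≈ 1.02e-19` (relative to the incident
beam — 20 cm of tissue absorbs most of the signal), carries total intensity
`I_t ≈ 2.7e-19 nm⁻¹`, and is smeared to a HWHM of `Δq ≈ 1.34 nm⁻¹` by the
target's 4 cm depth extent. Scanning a synthetic head phantom with an
off-center 1.5 cm disk lobe ranks every row and column path:

```r
spec <- phantom_spec(grid = c(180, 180), pixel_size = 0.1,
  head  = list(center = c(9, 9), semi_axes = c(8, 7)),
  lobes = list(list(center = c(4.5, 9), semi_axes = c(1.5, 1.5))))
mask   <- make_embedded_disk_mask(spec)
ranked <- evaluate_mask_scan(mask, default_medium(),
                             beam_geometry(20, energy_keV = 60))
head(ranked[, c("path", "l", "r_t_eff", "I_p", "delta_q", "omega", "omega_norm")], 3)
#>          path   l r_t_eff      I_p delta_q    omega omega_norm
#> 211 column 31 9.4     0.4 2.45e-18   0.268 1.28e-36      1.000
#> 212 column 32 9.6     0.7 2.31e-18   0.468 1.11e-36      0.868
#> 213 column 33 9.8     0.8 2.17e-18   0.535 9.64e-37      0.755
```

The best paths are the short chords grazing the lobe's edge nearest the head
boundary: because `Ω ∝ e^(−2μl)/l` under uniform attenuation, dose-efficient
conspicuity favors the shortest path that still crosses the target (see the
methods vignette, `vignettes/beam-orientation-model.Rmd`).

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/saxsbeam.R phantom --out head.pgm --head 9,9,8,7 --lobe 4.5,9,1.5,1.5
Rscript inst/cli/saxsbeam.R scan --mask head.pgm --pixel-size-cm 0.1 --out ranked.tsv --top 10
Rscript inst/cli/saxsbeam.R sweep --name target_size --out sweeps/
```

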