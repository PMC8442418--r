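---
title: "Modeling deep-target SAXS profiles and optimizing beam orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deep-target SAXS profiles and optimizing beam orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsbeam)
```

## The problem

Small-angle X-ray scattering (SAXS) carries nanoscale structural signatures:
amyloid fibrils, for instance, scatter coherently at the momentum transfer
corresponding to their 4.7 Å cross-β sheet spacing. Interrogating such a
target deep inside a large attenuating object — an amyloid-rich lobe inside a
human head — with an X-ray pencil beam poses two competing problems:

1. **Attenuation.** The beam and the scattered rays are exponentially
   attenuated along their whole path through the object, so longer chords
   cost signal and deliver more dose.
2. **Smearing.** The detector assigns each scattered photon a scattering
   vector assuming the scatter happened at one nominal distance. Scatter
   events spread over an extended target actually occur over a range of
   distances, so the recorded peak is smeared in `q`.

`saxsbeam` implements a single-scatter forward model of both effects, and a
figure of merit that ranks candidate beam paths by signal conspicuity per
unit dose, over analytic scenes (spheres and ellipses) or segmented 2D
raster masks of arbitrary shape.

## The forward model

### Scattering vector and its geometric spread

The scattering vector is `q = 4π sin(θ)/λ` with `2θ` the scattering angle;
all functions in the package take the **half** angle `θ` and say so in their
names and arguments. The wavelength comes from the beam energy via
`λ [nm] = 1.23984193 / E [keV]`; the default energy is 60 keV, a typical
diagnostic-range choice for head-penetrating beams. The default central
scattering vector `q_center = 13.4 nm⁻¹` is `2π / 0.47 nm`, the amyloid
cross-β spacing; both are configuration parameters, not model constants.

For a target of radius `r_t` centered at mean target-to-detector distance
`L0`, the relative spread of recorded `q` values is modeled by the one-sided
geometric construction

```
Δq/q = 2 − 2 / ( sin θ · sqrt( ((L0 + r_t)/(L0 tan θ))² + 1 ) )
```

(`relative_q_spread()`). It vanishes exactly for a point target, grows with
`r_t`, and shrinks with `L0`; to first order in small angles it equals
`2 r_t / (L0 + r_t)`. This closed form is a one-sided (far-edge)
construction and is used exactly as written; the package's independent
cross-check is the symmetric per-slice ray trace in `apparent_q()`, which
maps a scatter event at distance `L_event` to the `q` a detector calibrated
for `L0` would record. The two constructions agree to `O((r_t/L0)²)`, which
the test suite asserts up to `r_t/L0 = 0.15`.

### Relative intensity

The scattered intensity relative to the incident beam is the attenuated
density integral

```
I/I0 = σ · exp(−μ l) · ∫ ρ_t(x) dx
```

with `σ` the differential scattering cross-section per scatterer, `ρ_t` the
scatterer number density (uniform by default, or a `density_profile()`),
`μ` the linear attenuation coefficient shared by target and object, and `l`
the total beam path length through the object. A single exponential with the
*unscattered* beam's path length is used: `scatter_event_path_length()`
shows, by solving the scattered ray's exit segment with the law of sines,
that at SAXS angles (`2θ ≈ 0.04 rad`) the total path differs from the
straight chord by well under 1% wherever the scatter happens.

Default medium values are `μ = 0.30 cm⁻¹` (gray/white matter in the
diagnostic range), `ρ_t = 5.5e5 cm⁻³` and `σ = 5e-23 cm²`
(`default_medium()`).

### Step profile and detector smearing

`build_step_profile()` spreads the total intensity over apparent `q`: each
slice of the target maps to the apparent `q` of its own detector distance,
and the per-bin deposit is computed exactly by inverting that mapping at the
bin edges (no slice sampling noise). The result is a near-rectangular step
centered on `q_center` whose width matches the geometric spread to first
order and whose integral is normalized to `I/I0` exactly, so the total
intensity is independent of grid resolution.

Detector degradations are modeled by convolving the step with a **unit-area
triangular kernel** whose base width is 0.35 times the geometric `q` spread
(`make_triangular_kernel()`, `smear_profile()`). "Width" is read as the full
base of the triangle, the natural support measure for a unit-area kernel.
Convolution is exact discrete convolution; the output grid is extended by
the kernel half-width on each side and total area is conserved to better
than `1e-6` relative (asserted in tests).

### Profile summaries and figure of merit

Three summaries feed the path score (`summarize_profile()`):

* `I_p` — peak relative intensity (maximum sample);
* `I_t` — total relative intensity (trapezoidal area under the profile);
* `Δq` — half-width at half-maximum, defined via the **outermost** crossings
  of half the peak with linear interpolation. Outermost crossings make the
  measure deterministic on flat-topped smeared steps and recover `w/2`
  exactly in the ideal-rectangle limit.

The figure of merit is

```
Ω = I_p · I_t / (l · Δq)
```

rewarding a tall, intense, sharp peak per unit dose (dose taken proportional
to the path length `l`). `rank_paths()` sorts candidates by `Ω` and reports
`Ω/Ω_max` within the scan invocation; exact ties break deterministically by
orientation then index. Radiosensitive structures (cornea, optic lens, oral
cavity) are handled as an *optional* exclusion policy: by default paths
crossing an excluded region are kept and named in a warning, mirroring a
planning workflow in which exclusion is a human decision; `exclusion =
"drop"` removes them before normalization.

## Raster masks

Segmented 2D scout images enter as labeled masks (`read_mask()`): labels 0
(background/air), 1 (object), 2 (target), 3 (excluded), stored as integer
CSV or as 8-bit grayscale PGM/PNG with the fixed mapping 0, 85, 170, 255.
`trace_axis_path()` measures a full grid row or column: the attenuation
length is the pixel count of in-object material times the pixel size, and
the effective target radius is half the traversed target extent. Target
pixels count toward `l` by default because target and object share `μ`; the
alternative convention (object pixels only) differs by `2 r_t_eff` and is
available via `include_target_in_path = FALSE`. Indices are 1-based, as
everywhere in R. Only Cartesian (axis-aligned) paths are supported; oblique
rasterization is out of scope.

`evaluate_mask_scan()` composes the pipeline per path — measure, model,
summarize, score — and ranks. Paths that miss the target get `Ω = 0` and
`candidate = FALSE` rather than an error so whole-mask scans always
complete. `L0` is held constant across a scan, consistent with a fixed
detector and the small depth variation of one head.

## Synthetic phantoms and scene sweeps

`make_embedded_disk_mask()` rasterizes an analytic phantom — elliptical head,
elliptical/disk lobes, optional excluded zones — by membership tests at pixel
centers (no anti-aliasing, so labels are unambiguous and deterministic).
Optional salt-and-pepper label noise on the object/target boundary, behind a
fixed seed, supports robustness checks of the pixel-counting path
measurements; it is off by default.

`sweep_configs()` returns the canonical one-parameter scene sweeps used in
tests and examples. Their values are the study conditions of the modeled
scenarios:

| sweep | varied | fixed |
|---|---|---|
| `object_size` | `R_o` = 4…10 cm | `r_t` = 2 cm, `L0` = 20 cm |
| `target_location` | `L0` = 18…22 cm | `R_o` = 10 cm, `r_t` = 2 cm |
| `incidence_angle` | impact parameter 0…6 cm | `R_o` = 10, `r_t` = 2, `L0` = 20 |
| `ellipse_angle` | incidence angle 0…π/2 | `a` = 1, `b` = 3, `R_o` = 10, `L0` = 20 |
| `target_size` | `r_t` = 0.5…3 cm | `L0` = 20 cm, bare target |
| `medium` | — | `r_t` = 0.5, `R_o` = 10, `L0` = 20 |

One modeling decision deserves emphasis. In the **target-size sweep** the
target is *bare*: its attenuation path is its own diameter (`l = 2 r_t`).
With a fixed surrounding object the area-conserving step model makes the
peak height essentially independent of target radius (total intensity and
step width both scale linearly with `r_t`), and only the self-attenuation of
a growing target produces the expected behavior — larger targets yield lower
peaks and wider smearing. The sweep therefore isolates exactly the
target-size effects; embedded variants can be built directly with
`scatter_scene()`.

A consequence of the same scaling worth knowing before scanning masks: for
paths through a *uniformly attenuating* object, `I_p ∝ exp(−μl)` and
`I_t/Δq` is radius-independent, so `Ω ∝ exp(−2μl)/l` and the ranking is
governed by path length alone (with only a weak second-order preference for
larger targets among equal-length paths). The optimizer therefore favors the
shortest chord that still crosses the target — a grazing path near the
object boundary — rather than the path through the target center. This is a
property of the figure of merit, not a numerical artifact.

## Numerical choices

* **q grid**: uniform, default 2048 samples spanning
  `q_center ± 1.5 ×` the geometric spread, leaving margin for the kernel
  (`default_q_grid()`). A grid that cannot contain the step support raises
  an error naming the required span.
* **Kernel discretization**: the kernel requires at least ~4 grid steps per
  base width; with the default grid the kernel spans ~240 samples, far above
  the floor. Zero spread yields the identity kernel.
* **Degenerate inputs**: profiles that never fall below half-maximum at the
  grid edges raise an error (grid too narrow) rather than returning a
  truncated HWHM; beams that miss the object return a flagged zero chord.
* **Tie-breaks**: exact `Ω` ties rank by (orientation, index) ascending.
* **Output formatting**: the CLI and table writers use fixed 9-significant-
  digit scientific notation so repeated runs are byte-identical.

Problem sizes used in the shipped tests — 180×180-pixel phantoms at 0.1
cm/pixel, 1024–2048-point q grids, full row+column scans (~360 paths) — run
the whole pipeline in well under a second per scan and were chosen as
representative of a 2D scout-image planning task.

## What the synthetic data does and does not show

The phantom generator emulates the *geometry* of a segmented scout image:
convex head, compact lobes, radiosensitive zones, raster quantization of
path lengths and target extents. It does not emulate heterogeneous
attenuation (skull vs. soft tissue), non-uniform scatterer density inside a
lobe, background scatter from non-target tissue (the model is explicitly
background-subtracted), multiple scattering, polyenergetic beams, or
detector-specific blur beyond the triangular kernel. Passing tests on
phantoms therefore validate the geometry → profile → ranking pipeline, not
the absolute scale of real acquisitions: published per-path values from a
real segmentation (see `reference_path_summaries()`) depend on the original
mask and central `q`, and the package checks ratio-level consistency
(`Ω/Ω_max`, spread of `Ω` in decades) rather than absolute regeneration.

## Known limitations

Single scattering only; one attenuation coefficient for the whole object;
axis-aligned mask paths; solid-angle variation across the detector neglected
(it is negligible over the small angular range involved); the radiosensitive
exclusion is a binary per-path flag, not a per-pixel dose weighting.
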