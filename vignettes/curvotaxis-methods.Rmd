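---
title: "Quantifying curvotaxis on sinusoidal landscapes: models, conventions and defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying curvotaxis on sinusoidal landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvotaxis)
```

## The landscape model

All analyses in this package are built around cell-scale hills-and-valleys
substrata described by the sum of two perpendicular sinusoids,

$$z(x, y) = B\left[\cos\left(\tfrac{2\pi x}{P} + \phi_x\right) +
\cos\left(\tfrac{2\pi y}{P} + \phi_y\right)\right] + z_0,$$

with component amplitude $B$ (µm), axis period $P$ (µm) and peak-to-valley
range $4B$. Surfaces are named S$\langle$PV$\rangle$/$\langle P\rangle$:
S10/100 is the 10 µm peak-to-valley, 100 µm period lattice
(`sinusoidSpec("sum", amplitude = 2.5, period = 100)`).

The same surface can be written as a *product* of two cosines on the lattice
diagonals, with amplitude $A = 2B$ and period $\sqrt{2}P$ (the identity
$\cos a + \cos b = 2\cos\frac{a+b}{2}\cos\frac{a-b}{2}$). Both forms are
first-class `SinusoidSpec` objects. The sum form is the canonical internal
representation; the product form is what areal metrology fits, because the
measured product axes are the lattice diagonals — which is why a 100 µm
lattice reports a fitted period near $141.4$ µm. The two conventions for
"amplitude" (10 µm peak-to-valley; ~5 µm fitted product amplitude) are kept
strictly apart in the reports (`fittedAmplitude` vs `heightRange()`).

### Coordinates and sign conventions

* Units are micrometres everywhere; time is minutes.
* Height maps are matrices with rows indexing $y$ and columns indexing $x$,
  sampled at pixel centres; the origin is the lower-left pixel centre.
* The surface normal points up. Mean curvature is
  $H = \tfrac{1}{2}(\kappa_1 + \kappa_2)$, computed from the graph formulas
  with exact partial derivatives (`analyticCurvature()`) or second-order
  central differences (`discreteCurvature()`). **$H > 0$ is concave
  (valley), $H < 0$ convex (hill).** The literature rarely fixes this sign;
  we state it because every downstream statistic ("density on concave")
  depends on it.
* Border pixels of a discrete curvature field use one-sided stencils and are
  flagged (`@interior`) as lower accuracy.

## Isoheight bands and positioning statistics

Landscapes are segmented into five areas delimited by isoheight contour
lines (`segmentHeightBands()`), band 1 the lowest. Default band edges are
evenly spaced between the minimum and maximum height (`equal_height`);
contour spacing is not standardized anywhere, so an `equal_area` quantile
mode is available behind a flag. Pixels are assigned to half-open intervals
$[e_i, e_{i+1})$ with the closed top band, so ties at edges go to the upper
band deterministically.

Band areas are *projected* (2-D) areas: nuclei are counted in projection,
and for a 1:10 aspect-ratio lattice the true-area correction is at most a
few percent. A `area = "surface"` option applies the local
$\sqrt{1+|\nabla h|^2}$ correction for sensitivity checks.

"Concave" for the concave-fraction statistic means bands 1–2 — the bottom
40% of the height range. The cut is a parameter (`concaveBands`) because no
standard definition exists.

Two significance routes are implemented and reported side by side:

* `replicateTTest()` — the experiment-level statistic: a two-sided
  one-sample Student's *t*-test of per-replicate concave fractions against
  the area-expected fraction (typically three independent experiments).
* `csrTest()` — a Monte-Carlo complete-spatial-randomness test that
  resamples the observed number of points uniformly over the banded region
  and computes a one-sided enrichment p-value
  $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{MC}+1)$. It supplements, not
  replaces, the replicate test, and is calibrated: its type-I error at
  $\alpha = 0.05$ sits in $[0.03, 0.07]$ under its null (checked in the
  test suite with 500 null datasets).

Point heights are always looked up from the height map at the point's
containing pixel; a z column in input files is never trusted.

## Metrology

`fitSinusoid()` reproduces the standard surface-quality workflow: the map
is rectified with a least-squares polynomial of total degree 1, then the
product-form model (amplitude, period, two phases, axis orientation, offset
*and a residual plane*) is fitted by nonlinear least squares. The residual
plane term matters: rectifying a finite patch of a sinusoid legitimately
leaves a small tilt (the first moment of a cosine over whole periods is not
zero), and without the plane term that tilt would put a hard floor under
the residual. The "shape" statistic is the standard deviation of measured
minus fitted heights.

The fit is staged for robustness: (1) the two dominant 2-D spectral peaks
initialize two plane waves; (2) the wave vectors are refined with all
linear coefficients profiled out (variable projection); (3) the product
parameters are polished jointly with an analytic gradient, with a 4×4 phase
multi-start as a fallback whenever the polish explains less than 98% of the
height variance. On ideal maps the residual is at numerical zero; across 50
random-phase fixtures with 0.05 µm noise, amplitude and period are
recovered to better than 1% (asserted in the suite).

Roughness separation follows the cutoff convention of areal-texture
standards: the reference (low-pass) surface transmits
$1/(1+(\lambda_c/\lambda)^4)$ of the amplitude at wavelength $\lambda$ —
exactly 50% at the cutoff $\lambda_c$ (5 µm by default) and ~100% for long
wavelengths — and the roughness map is the complement
(`highpassSpline()`, curve exported by `splineFilterTransmission()`). The
filter is applied in the frequency domain on a mirror-extended grid to
avoid wrap-around edges. The exact recursive coefficients of the standard
spline filter are not public in any of our sources; the transmission
contract above is what the tests pin down. $S_a$ is the arithmetic mean
deviation of the (filtered) heights (`computeSa()`).

`metrologyReport()` chains the steps and, for fine-pitched maps, fits the
form on a decimated copy (default cap 4·10⁴ pixels — the form only lives at
long wavelengths) before subtracting it at full resolution.

## Trajectories

* `basinMap()` labels each pixel with the minimum its steepest-descent path
  reaches (8-connectivity, drop per centre distance, plateau ties to the
  smallest linear index). For ideal lattices the basins reproduce the
  Voronoi cells of the minima to within a pixel.
* `speedByHeight()` attributes each segment's in-plane speed to the band of
  the segment midpoint. Speeds are in-plane because tracking is done on
  maximum projections; a 3-D arc-length correction would require trusting
  interpolated heights between samples.
* `detectValleyTransitions()` debounces the basin-label sequence: a new
  basin must persist at least `minDwell` frames (default 3) before a
  valley-to-valley transition is emitted, so one-frame boundary flickers
  during a saltatory crossing do not count. No published criterion exists
  for a "completed" valley change; 3 frames at the default 10 min sampling
  means a basin must hold for half an hour.
* `distanceToNearestMinimum()` is in-plane Euclidean (ties to the smallest
  index); a geodesic alternative was considered and rejected as
  over-engineering at 1:10 aspect ratios, where the difference is ≪ 1%.
* `nucleusOffsetAlignment()` averages the cosine between the
  centroid-to-nucleus vector and the centroid-to-nearest-minimum vector
  over pairs with an offset of at least 0.5 µm (sub-pixel offsets carry no
  direction information). The statistic is invariant under global rigid
  motions, which the suite asserts.

## The synthetic-data generator

No public dataset accompanies the imaging experiments this pipeline
quantifies, so the package ships a generator (`simulateCurvotaxis()`,
`placePointsBoltzmann()`, `makeNoisyHeightMap()`) that emulates them. The
migration model is a biased persistent random walk embodying the
nuclear-sliding picture of curvature-guided migration — the nucleus slides
toward concave, altering the cell's random walk:

$$\theta_{t+dt} = \theta_t + \sqrt{2\,dt/\tau}\;\eta, \qquad
\mathbf{x}_{t+dt} = \mathbf{x}_t + \left[v_0(1+\lambda\tilde z)\,
\varepsilon_t\,\hat e(\theta) - \chi \nabla h\right] dt$$

with reflecting borders, $\tilde z$ the height normalized to $[-1,1]$ and
$\varepsilon_t$ a mean-1 lognormal frame-to-frame speed fluctuation. The
nucleus is placed downhill of the centroid, offset by
`nucleusGain`·`cellRadius` scaled by the local relative slope, plus
isotropic jitter.

These equations are the package's own minimal model — the source biology
proposes the mechanism, not kinetics. Design notes:

* the drift rides on $-\nabla h$ (slope), not curvature: on sinusoids,
  height, slope and mean curvature are phase-locked, so either choice
  produces the same phenomenology, and slope is numerically robust;
* $\varepsilon_t$ exists because measured cell speeds are strongly
  variable frame to frame; without it the model's speed magnitude would be
  deterministic and speed-difference tests against it degenerate;
* reflecting borders keep the stationary distribution well defined on a
  finite field (periodic wrapping is a config choice away in extent).

Defaults (`simulationConfig()`): 200 cells on a 2×2-period S10/100 field,
`dt` 10 min, 20 h duration, `v0` 0.3 µm/min, persistence 3 min,
`speedCV` 0.3, cell radius 15 µm — slow mesenchymal-like movers sampled at
typical time-lapse cadence; the short persistence keeps the unbiased walk
well mixed within a run. The bias grid used in the dose-response property
is $\chi \in \{0, 0.01, 0.03, 0.1, 0.3\}$ µm/min per unit slope; with the
default motility this spans "no detectable enrichment" to "nearly all
nuclei in the valleys", which is the regime the assays must resolve.

`placePointsBoltzmann()` draws nuclei from the stationary-like density
$\propto e^{-\beta z}$ by rejection sampling — a fast stand-in used to
calibrate the positioning statistics independently of the walk.

Occupancy statistics on simulated runs are computed on positions pooled
over the second half of the run rather than the final frame only: the
late-time distribution is stationary, and pooling uses the fixed cell count
efficiently.

What the generator does *not* emulate: cell division (and the transient
loss of curvature sensitivity around it), cell–cell interactions and
epithelial crowding, detailed nuclear mechanics, segmentation noise in
positions. Passing tests therefore demonstrate that the *pipeline measures
what it claims on data with known ground truth* — not that the biological
parameters are those of any particular cell type.

## Morphometrics

`shapeFromMask()` computes nuclear volume as voxel count × voxel volume and
surface area on an iso-surface mesh: the binary mask is mollified with a
small Gaussian (σ = 1.2 voxels) and the 0.5 level set is triangulated by
marching tetrahedra. Voxel-face counting was rejected because it
overestimates the area of any oblique surface (by up to $\sqrt{3}$) and
systematically depresses sphericity. Sphericity is the isoperimetric ratio
$\Psi = \pi^{1/3}(6V)^{2/3}/A$ — the common operational definition in
imaging suites. Benchmarks pinned in the suite: a radius-20 sphere measures
$\Psi \ge 0.99$ (volume within 1%), a 2:1:1 prolate spheroid matches its
closed-form $\Psi \approx 0.929$ within 1%, and $\Psi$ is exactly
scale-invariant. The mollifier trades a sub-percent curvature-dependent
area bias for the removal of staircase noise; σ was fixed against the
sphere benchmark and is exposed as `smoothSigma`.

## Numerical sizes used by the checks

The shipped suite and the acceptance script run on desk-scale problems
chosen as the package's own validation sizes: 300 µm maps at 0.5–3 µm
pitch for surface and metrology work, 200-cell simulations of 20 h at
10 min cadence, 500 null datasets for test calibration, and ≤ 10⁵-voxel
masks for morphometrics. All stochastic steps take explicit integer seeds
and are bit-reproducible.

## Known limitations

* The curvature field of a measured (noisy) map amplifies noise through the
  second derivatives; filter before classifying curvature on real data.
* `equal_area` band edges use height quantiles, which on heavily quantized
  height data may not be strictly increasing; such maps are rejected rather
  than silently merged.
* The fitted axis orientation is reported modulo π/2 symmetry of the
  lattice; compare orientations through the lattice symmetry group.
* The simulator's parameters are phenomenological; fitting them to real
  tracks (e.g. by matching speed distributions and transition rates) is out
  of scope here.
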