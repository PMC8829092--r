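---
title: "spt2d: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spt2d: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spt2d)
```

`spt2d` covers the full single-particle-tracking chain — trajectory
simulation, synthetic movie rendering, detection and linking, and
MSD/ADC-based diffusion-model inference. This vignette explains the
underlying models, the estimators and their numerical details, the choices
made where the design was genuinely open, and the limits of what the
synthetic validation can show.

## Trajectory model and canonical units

A `Track` is a 2D trajectory sampled at a strictly uniform interval
`dt` (relative tolerance 1e-6, enforced at construction — the whole
analysis stack assumes constant spacing). Internally everything is SI:
seconds and metres. Unit conversion happens only at the CSV boundary
(`readTracks(..., lengthUnit = "um")`), which avoids scale bugs in
formulas that mix `t`, `dt` and squared lengths. CSV files carry columns
`t,x,y` plus `id` for multi-track files, in any order; time is always
seconds (no time-unit option is exposed — a deliberate simplification,
since mixed time units are a rarer dialect than µm/nm coordinates).
Tracks with fewer than two points are rejected: no displacement, no MSD.

## Time-averaged MSD

`computeMSD()` uses all overlapping windows: at lag `n` it averages the
squared displacement over the `N − n` available start points. The
overlapping (time-averaged) estimator is unbiased for stationary
increments, but its errors are strongly *correlated across lags* — the
same displacements enter many lags — which matters later for model
selection. A brute-force double-loop oracle pins the implementation in the
test suite at 1e-12 relative on tracks up to N = 50.

`fitMSD()` fits, by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, max 1000 evaluations, ftol/ptol/gtol 1e-12),

$$\mathrm{MSD}(t_n) = 4 D t_n^{\alpha} + 2\delta^2 - 8 D R t_0,$$

with $\alpha \equiv 1$ for the linear model. Conventions and defaults:

* `D ≥ 0`, `δ² ≥ 0`. The blur term $-8DRt_0$ carries the negative part of
  the apparent intercept, so the constraint on `δ²` stays physical.
* `R` (dimensionless, `[0, 1/4]`) is a property of the illumination/shutter
  profile, supplied by the user and never fitted. Default 0 (no blur
  correction). `R` depends on the acquisition hardware, not the sample, so
  treating it as data-fitted would be over-parameterisation.
* Fit range: exactly one of `fitMaxTime` (seconds) or `fractionFitPoints`;
  when neither is given the first 25% of lags are used. The range must be
  chosen deliberately: short-lag points carry the diffusion information for
  free diffusion, long-lag points are needed to see confinement plateaus,
  and the long-lag tail of a single-track time-averaged MSD is dominated by
  correlated noise.
* Initial values: `D` from the slope of the first two lags, `δ² = 0`,
  `α = 1`. Parameter errors are the square roots of the diagonal of
  `RSS/(n−k) · (JᵀJ)⁻¹`; on degenerate systems (exact data, RSS ≈ 0) they
  are reported as `NA` rather than invented.
* `fixDelta` pins the localisation error when it is known from immobilised
  reference particles; by default `δ²` floats, which is preferable for
  moving particles whose localisation is necessarily worse than that of
  immobile references.

## Apparent diffusion coefficient and model registry

The ADC transform divides out the Brownian time dependence,

$$D_{app}(t_n) = \frac{\mathrm{MSD}(t_n)}{4 t_n (1 - 2R/n)},$$

with `n` the integer lag index. "Apparent" because localisation error is
still present: every registered model carries the additive term
$\delta^2 / (2t(1 - 2R\,dt/t))$ with `δ` (metres, ≥ 0) as the fitted
parameter. Built-ins:

| model | free parameters | D(t) |
|---|---|---|
| `brownian` | D, δ | $D$ |
| `confined` | D, δ, τ | $D\,(\tau/t)(1 - e^{-t/\tau})$ |
| `hop` | D_M, D_μ, δ, τ | $D_M + D_\mu(\tau/t)(1 - e^{-t/\tau})$ |

The confined law tends to `D` as `t → 0` (series: $1 - t/2\tau + \dots$)
and decays to zero transport at long times; with the confinement size
relation $D_\mu = L^2/12\tau$ the long-time MSD plateau is $L^2/3$. Initial
values (`D ~ 0.5e-12 m²/s`, `δ ~ 2e-9 m`, `τ ~ 1e-2 s`) are at the scale of
membrane-protein tracking experiments; bounds keep all parameters
non-negative (τ ≥ 1e-12 s avoids a division by zero, and is far below any
resolvable residence time).

`ModelRegistry` is an ordered set with unique names; `registerModel()` adds
custom `DiffusionModel` objects (curve function, bounds, initial values)
that the pipeline fits exactly like the built-ins. Registration order is
meaningful only for tie-breaking.

Model selection uses `BIC = k·ln(n) + n·ln(RSS/n)` on the fitted range
(`n` points, `k` free parameters); the lowest BIC wins. Ties (ΔBIC <
1e-9, as arise when a duplicated model is registered) go to the
first-registered model and are flagged in the report. Fits that do not
converge carry `RSS = ∞`, are excluded from the argmin, and keep their
diagnostic message; the analysis aborts only if *no* model converges. A
two-sample Kolmogorov–Smirnov statistic between the ADC data and the
fitted curve over the fit range is recorded per model as a goodness
check. The two-sample form was chosen because the theoretical
distribution of ADC values under a fitted model is not available in
closed form; the statistic is advisory and never overrides BIC.

### BIC on time-averaged data: a caution

BIC's penalty calibration assumes independent residuals. Time-averaged
single-track MSD/ADC values violate that assumption badly: their errors
are smooth, correlated excursions that a nested model with one extra
parameter can absorb far beyond the nominal χ²₁ expectation. The test
suite quantifies the consequence: on single 5000-step Brownian tracks the
free-diffusion model wins against `confined`/`hop` in roughly half of the
tracks at typical fit ranges (approaching ~70% only for very short
ranges), even though parameter recovery is accurate — the identical
selection machinery picks `brownian` in 30/30 synthetic data sets with
*independent* noise. Consumers should treat per-track best-model calls on
free-diffusion-like data as noisy votes and aggregate over tracks (via
`adcSummary()`); detection of genuine confinement is far more reliable
(95% of HP = 0 hop simulations select a confinement-bearing model in the
acceptance run).

## Simulators

`simulateBrownian()` draws per-axis displacements $\sqrt{2D\,dt}\cdot
\mathcal N(0,1)$ — the variance that makes the per-step MSD equal
$4D\,dt$ in 2D — on a square domain of side `L` with reflecting
boundaries (boundary handling is not dictated by the physics of the
sampler; reflection was chosen because it preserves the uniform invariant
density). The particle starts at the centre; a track has
`floor(Tmax/dt) + 1` points; a fixed `seed` reproduces the walk bitwise.
Optional `quantize` rounds positions to a `dL` grid (off by default; it
exists to emulate detectors that report integer grid positions).

`simulateHop()` adds a Voronoi compartmentalisation: seed points uniform
in the domain (own `voronoiSeed`), compartment membership by nearest seed
(equivalent to the Voronoi diagram, no polygon construction). A proposed
step that would change compartment is accepted with hopping probability
`HP`; otherwise it is redrawn, up to 100 attempts, after which the
particle stays put for that step (the event is counted in the
`rejectedSteps` attribute — in practice it is rare for step sizes below
the compartment scale). `HP = 0` is confined diffusion (the compartment id
never changes); `HP = 1` accepts every proposal and is statistically free
diffusion; a single compartment short-circuits to the exact
`simulateBrownian()` stream.

Default study conditions used in the validation suite (chosen once, at the
scale of membrane SPT): `D = 1e-12 m²/s`, `dt = 1e-4 s`, `Tmax = 0.5 s`
(5000 steps), domain `L = 1e-5 m`; for confinement studies 100
compartments, i.e. a mean equivalent cell diameter of 1.13 µm and a
residence-time scale `d²/12D ≈ 0.1 s`, well inside the measurement window
so the MSD plateau is actually sampled.

## Synthetic movies

The renderer maps track points onto a grid with spatial pitch `rXY` and
frame interval `rT`: index `m = round((x − x_min)/r)` (R's
round-half-to-even). The grid spans the min/max extents over all tracks
(`side = round(extent/r) + 1`; the `squareGrid` option takes the enclosing
square). An optional `padPx` margin widens the grid so that PSF kernels
and refinement windows fit around border spots; the default 0 keeps the
exact extent-derived shape.

Stages, in order: i.i.d. Gaussian background `N(μ_bg, σ²_bg)` everywhere;
delta spots of amplitude `C` (the contrast `I_p − μ_bg`; negative values
are allowed for absorption-type contrast) at the discretised positions;
optional PSF convolution of the spot field (zero padding; a 3D PSF stack
contributes its central, in-focus slice; unit-sum normalisation by default
so total spot intensity is conserved, or `normalizePSF = FALSE` to
preserve *peak* contrast — the convention in which iSCAT contrast is
usually quoted); background added outside the convolution; finally
pixelwise Poisson noise with λ equal to the pre-noise intensity (negative
λ clipped to zero with a warning — keep `μ_bg ≳ 3σ_bg` to avoid biasing
the noise floor). A fixed `noiseSeed` yields a bitwise-identical movie.

TIFF export writes one page per frame. The underlying TIFF writer stores
data in [0, 1], so all bit depths (8, 16, float32) are min–max scaled and
the scaling constants recorded in a JSON sidecar next to the file;
`readTIFFStack()` inverts the scaling automatically, making the export a
lossless round trip at float32 precision.

## Tracker

*Pre-processing* follows the iSCAT convention: divide by the flat field
(pixel-wise temporal median over the first `medianWindow = 1000` frames),
subtract the temporal-mean background, min–max normalise. Flat-field
pixels below 1e-6 of the global median are floored to that median before
division. Each stage can be disabled — and should be, for movies whose
background is already uniform: with a slowly diffusing particle the
temporal median/mean contain a smeared ghost of the spot itself, and
subtracting it measurably distorts sub-pixel localisation (about half a
pixel in the round-trip test conditions). This is a known limitation of
temporal background estimation, not specific to this implementation.

*Detection* convolves the frame with a zero-sum negated
Laplacian-of-Gaussian kernel of scale `sigma` (bright spots by default;
`darkSpots` negates the image first). The global threshold
`T = μ + c·σ` is computed on the *filtered* image (the filtered image is
where the matched-filter statistics are meaningful; computing them on the
raw frame would couple the threshold to background structure the filter
removes); default `c = 3`. Candidate peaks are strict local maxima above
`T` whose above-threshold footprint diameter lies within
`peakSizeLimits` (diameter = the larger bounding-box side of the
connected component, in pixels). Each candidate is refined by the
radial-symmetry centre within an odd `roiSize` window; windows off the
image edge drop the detection with a message.

*Radial-symmetry localisation* computes image gradients on the half-pixel
grid via diagonal differences, smooths them with a 3×3 boxcar, and finds
the least-squares intersection point of the gradient lines, weighted by
squared gradient magnitude over distance from the magnitude centroid. It
is non-iterative and, on synthetic Gaussian spots, sits within a few per
cent of the Gaussian-fit gold standard (the acceptance run measures
~3e-4 px worst-case error noiseless and ~0.08 px per-axis RMS at peak
SNR 10 — essentially the information-theoretic limit, since the
Cramér–Rao bound for the mean Euclidean error at that SNR is ~0.1 px
regardless of estimator). It assumes radially symmetric spots; asymmetric
PSFs need a different refinement stage.

*Linking* runs the Hungarian algorithm (an O(n³)
potentials/augmenting-path implementation, `solveAssignment()`, verified
against exhaustive permutation search) on the Euclidean distance matrix
between open tracks and the detections of each frame; assignments beyond
`maxDistance` are forbidden. Unmatched detections open new tracks; tracks
unmatched for more than `maxGap` frames close; gap frames inside a track
are filled by linear interpolation between the flanking detections
(the least-assumption interpolant for an unobserved diffusing particle).
Tracks shorter than `minTrackLength` frames are discarded.
`trackMovie()` composes the stages and converts to metres/seconds.

## Validation design and problem sizes

All validation data are generated in code; there are no stored fixtures.
The acceptance study (`scripts/acceptance.R`, ~2 min on one CPU) uses 50
Brownian tracks of 5000 steps for parameter recovery, 20 hop tracks for
confinement detection, 100 noise realisations for localisation precision,
10 seeds of a 1000-frame movie for the end-to-end round trip (30 nm
pixels, peak contrast 10 σ_bg over a Poisson-noised background), and
64×64×50 constant scenes for the noise statistics. End-to-end `D`
estimates fit only the first 10 lags: for free diffusion the short-lag
slope is where the Fisher information concentrates, and long lags add
correlated noise faster than signal.

What the synthetic data do *not* emulate: photophysics (blinking,
bleaching), spatially structured backgrounds, motion blur within the
exposure (the blur term models its effect on MSD, but rendered spots are
instantaneous), non-Gaussian camera noise, and particle–particle
proximity below the diffraction scale. Passing tests therefore demonstrate
correctness of the estimators and the pipeline plumbing under the stated
noise models, not robustness to every artefact of real data.

## Command-line interface and configuration

`inst/cli/spt2d.R` is a thin launcher over `runCLI()`, with subcommands
`simulate`, `movie`, `track`, `msd`, `adc`. Exit codes: 0 success, 2
usage/validation error, 1 runtime error. A YAML file passed as
`--config` supplies per-subcommand defaults which explicit flags override
(YAML was chosen as the configuration dialect because a parser ships with
the R ecosystem used here). Every stochastic subcommand takes `--seed`
and is reproducible under it.

## Known limitations

* Per-track BIC selection between nested diffusion models is optimistic
  for the larger model on time-averaged single-track data (see above);
  aggregate before concluding.
* The ADC/MSD fits are unweighted; long-lag points enter with the same
  nominal weight despite their larger variance. Choose fit ranges
  accordingly.
* Compartment ids are 1-based, following R indexing conventions.
* 3D trajectories, ensemble-averaged MSD estimators, anomalous-diffusion
  trajectory generators and AVI export are out of scope.
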