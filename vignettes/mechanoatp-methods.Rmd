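---
title: "Methods: quantifying mechanically stimulated ATP release"
author: "MechanoATP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mechanically stimulated ATP release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MechanoATP)
```

# Overview

Mechanically stimulated bone cells release ATP within seconds of membrane
deformation. That release drives paracrine calcium signalling in neighboring
cells, and its magnitude reflects the balance between membrane injury and
repair. MechanoATP implements the quantitative chain used to analyze such
experiments:

1. **Calcium transients** — parameterize the ratiometric Fura-2 response of a
   stimulated cell (amplitude, 10–90% activation time, decay constant) and
   quantify the secondary responsiveness of its neighbors.
2. **ATP quantification** — convert luciferin/luciferase reporter signals to
   concentrations through a log-log calibration, and estimate the amount a
   single cell released by fitting pericellular concentration profiles with
   the instantaneous plane-source diffusion law.
3. **Vesicle imaging** — detect quinacrine-positive vesicle puncta and call
   exocytosis events as abrupt fluorescence disappearances via temporal
   reversal of the stack.
4. **Membrane injury** — classify dye-leakage traces into minor /
   intermediate / severe injury, and bracket the membrane lesion radius from
   the permeability pattern of tracers with known molecular radii.
5. **Synthetic data** — generate every input above with embedded ground
   truth, so each stage is testable without access to raw recordings.

# Calcium transient parameterization

A trace is a uniformly sampled `FluorescenceTrace` with a stimulus time. The
baseline is the **median** of the pre-stimulus window (default 10 s, i.e.
20 samples at the 2 Hz acquisition standard); the median is robust to
single-frame artifacts, which is why it is preferred over the mean.

`characterizeTransient()` extracts, per the conventional definitions:

* **amplitude** — maximum post-stimulus value minus baseline. We checked the
  extreme-value bias of this estimator by simulation at the benchmark noise
  level (SNR 20) and found its median relative error well inside the 5%
  recovery tolerance, so no smoothing is applied before peak extraction.
* **t~act~ (10–90% activation time)** — time between the 10% and 90%
  amplitude crossings on the rising phase, linearly interpolated between
  bracketing samples. Noise can produce multiple crossings; ties are resolved
  by taking the *last* crossing before the peak. A rise faster than the
  sampling interval (an ideal step) is reported as a tenth of a sample
  interval and flagged `rise_unresolved` rather than zero, keeping the
  activation rate finite.
* **τ~decay~** — least-squares fit of `b + A·exp(-(t - t_peak)/τ)` over the
  deactivation segment, which runs from the peak to the first return to
  within 5% of baseline (or the end of the trace). The fit is initialized
  with τ₀ = time to fall to 37% of amplitude. A non-convergent fit leaves τ
  undefined (flag `decay_fit_failed`) while the other parameters are still
  returned.
* **activation rate** — amplitude / t~act~, undefined (an error on access)
  when there is no measurable response.

Only the first post-stimulus peak is parameterized; evoked responses in this
preparation are single transients, and later peaks are ignored by
construction of the decay window.

**Secondary responsiveness.** The criterion for a neighboring cell
"exhibiting a calcium elevation" is not standardized; we adopt an explicit
event-calling rule: a neighbor responds if its post-stimulus signal exceeds
its own baseline median by `kSd` (default 4) baseline-window standard
deviations for at least 2 consecutive samples. At 2 Hz this two-sample
persistence requirement suppresses single-frame noise excursions. A
zero-variance baseline gets a negligible additive guard so that flat traces
are non-responders without dividing by zero. The default `kSd = 4` is this
package's documented choice, not a value taken from any specific prior
analysis.

# ATP quantification

**Calibration.** Luciferase assays are close to power-law over several
decades, so standards are fitted as `log10(signal) = intercept +
slope·log10([ATP])`. The functional form is a package choice; the valid
range is pinned to the standards' span and any conversion outside it is
returned *flagged* as extrapolated rather than refused, because pericellular
concentrations legitimately span 0.05–80.5 µM.

**Plane-source model.** Release from a stimulated cell is idealized as an
instantaneous plane source: concentration at distance $x$ and time $t$ is

$$c(x,t) = \frac{\sigma}{2\sqrt{\pi D t}}\, e^{-x^2/4Dt},$$

with areal strength σ in amol/µm² and $D$ in µm²/s. Working in
µm/s/amol units makes 1 amol/µm³ = 1 mM, so unit conversion happens once, at
the return value (µM). The default $D$ = 330 µm²/s corresponds to the
conventional aqueous ATP diffusion coefficient of 3.3×10⁻⁶ cm²/s at 22 °C;
assay temperature may differ, so $D$ is an explicit parameter everywhere.

**Fitting.** With the release time fixed, the model is *linear* in σ and the
least-squares solution is closed-form, σ = Σmᵢcᵢ/Σmᵢ², where mᵢ is the model
at unit σ. This is exact, fast, and verified in the tests against both an
independent iterative fit and a dense grid search. An optional `fitT0` mode
fits a release-time offset jointly by nonlinear least squares (stimulus time
and actual release time can differ by ~1 s); on non-convergence it falls
back to the closed form with a flag. Observations are accepted as arbitrary
(x, t, c) triples — spatial profiles at fixed times, temporal decays at
fixed distances, or both jointly — because the model treats them
identically.

**Geometry.** The plane-source fit yields an areal strength; converting it
to a per-cell amount requires the effective release area, which is an
experimental quantity. `fitSourceAmount()` therefore takes `effectiveArea`
with *no default*: M = σ·area is only reported when the caller supplies the
cell cross-section, keeping the geometric ambiguity explicit instead of
hiding a guessed area inside the package.

**Bulk release.** For supernatant measurements the arithmetic is exact unit
bookkeeping: µM × µL = pmol, ×10⁶ = amol, divided by the cell count. The
dose–response of release against the number of media displacements is
fitted with the first-order rational form `y = a·x/(b + x)` — the simplest
rational function with the horizontal asymptote seen in saturating release
data; the order is a documented package choice.

# Vesicle imaging

**Preprocessing** runs bleach detrend (divide each frame by its whole-frame
median relative to frame 1), background subtraction (residual after a
median filter of radius 6 px, comfortably larger than the ~1.25 px punctum
radius), then a robust 1st–99th percentile rescale of the whole stack. The
order matters: detrending uses raw whole-frame medians, which background
subtraction would flatten to ~0.

**Punctum detection** is Laplacian-of-Gaussian blob detection at a single
scale (default 0.5 µm): maxima of the scale-normalized LoG response above
`median + 8·MAD` of the response image, followed by greedy non-maximum
suppression with mutual exclusion radius equal to the blob scale — two
puncta closer than that merge into the stronger detection, by construction.

**Event calling.** The field convention detects exocytosis as a *sudden
loss* of punctum fluorescence, distinguished from vesicles drifting out of
focus. Spark-detection plugins applied to temporally reversed stacks have
historically served this purpose, but their settings are rarely published;
this package defines a reproducible equivalent:

* Puncta are detected once on the average of the first 5 (pre-stimulus)
  frames, and each punctum's mean intensity in a fixed 1 µm disk is traced
  over all frames. We deliberately do **not** link detections frame-to-frame
  into tracks: a disappearance event leaves nothing to link, so track
  termination would truncate exactly the intensity step the caller needs,
  and adherent osteoblasts do not translocate on the 2-minute timescale.
* The time axis is reversed so a loss becomes a rise. A candidate event is a
  frame-to-frame increase exceeding `mean + k·SD` (default k = 4) of that
  punctum's own differences. The two largest-magnitude differences are
  excluded when computing the mean/SD — otherwise the event itself inflates
  the threshold it is tested against.
* The transition must *complete* within `maxRiseFrames` (default 2 frames =
  1 s at 2 Hz): the rise accumulated inside that window must account for at
  least 70% of the total level change across the transition (medians of
  4-frame flanks). Gradual fades spread their change over ≥ 20 frames and
  fail both the step test and the completeness test.
* The step must also be commensurate with the punctum: at least 35% of the
  punctum's elevation above its darkest level (`minDeltaFrac`). This rejects
  residual noise steps in the flat tail left behind by a completed fade.
* At most one release event is called per punctum — a vesicle releases its
  content once — which also guarantees the pigeonhole invariant that
  cumulative release can never exceed the basal density. Drops that leave
  substantial residual intensity are kept but flagged `partial`.
* Frames whose whole-field median jumps by > 20% (stage/focus artifacts) are
  masked from calling, and puncta within 2 px of the cell-mask boundary are
  discarded as edge artifacts.

Event calls are invariant to global intensity scaling (all thresholds are
SD- or fraction-relative), and an abrupt *appearance* can never be called
because only positive reversed-time steps are candidates.

Density normalization uses the projected cell area from the user-supplied
mask; whether historical analyses used projected or membrane surface area
is ambiguous, and projected area is the measurable choice. No automated
segmentation is attempted.

# Membrane injury and lesion bracketing

**Classification.** The qualitative trace taxonomy — fluorescence returns to
baseline (mIn), partially reduced (iIn), completely lost (sIn) — is made
operational through the floor-referenced retained fraction
`(plateau - floor)/(baseline - floor)`, clamped to [0, 1], with default
cutoffs retained ≥ 0.8 → mIn and ≤ 0.1 → sIn. The cutoffs are configurable;
the 0.8/0.1 defaults reproduce the visual taxonomy on well-separated traces
while remaining testable. Referencing a background floor makes explicit
what "complete loss" means in the presence of residual autofluorescence.

**Lesion radius.** Tracer radii follow Erickson's minimal-sphere relation
R(nm) = 0.066·MW(Da)^(1/3). This is a deliberate lower-bound convention: it
underestimates the hydrodynamic radius of polymer coils such as dextran, so
per-dye radii in the tracer table can be overridden. The lesion bracket is
then pure logic: the lesion must be at least as large as the largest
permeant tracer and smaller than the smallest excluded one; a permeant
tracer larger than an excluded one is reported as a data inconsistency
rather than silently ordered away. The shipped dye table uses 832 Da for
Fura-2 (pentapotassium salt) — the form is not standardized across studies,
so the value is an overridable default.

```{r lesion}
lesionRadiusBracket(defaultDyeTable())
```

# Synthetic data: what it emulates, and what it does not

Each generator is a pure function of (parameters, seed): the caller's RNG
state is saved and restored, and regeneration is bit-identical. Noise models
follow the physics of each signal: additive Gaussian for ratio traces,
mean-one lognormal for luminescence and concentration (multiplicative
instrument noise), and Poisson + Gaussian for camera frames (shot plus read
noise, scaled so the total SD at a punctum peak is amplitude/SNR).

* `simulateTransient()` — flat baseline, raised-cosine ("sigmoidal") rise
  with a requested 10–90% time, exponential decay. The rise duration is
  snapped to the sampling grid so the true peak falls on a sample; the
  ground-truth sidecar reports the actually generated t~act~.
* `simulateFieldRecording()` — a primary transient plus neighbors at 20–80
  µm; responders get transients delayed proportionally to distance
  (1 s + 0.05 s/µm), non-responders baseline noise.
* `simulateSourceProfiles()` — exact plane-source values on a grid
  respecting the 15 µm pericellular limit, times lognormal noise.
* `simulateVesicleStack()` — Gaussian puncta (σ = 0.5 µm, minimum spacing
  2 µm) on a smooth textured background inside a circular cell mask
  (defaults: 64×64 px at 0.4 µm/px, mask radius 9.5 µm, 20 puncta — chosen
  so the basal density is ~70×10⁻³ vesicles/µm², the physiological scale),
  2 Hz for 2 min, global exponential bleaching (τ = 200 s). Events remove a
  punctum in one frame; fades shrink linearly over 24 frames.
* `simulateInjuryCohort()` — class labels drawn at the requested fractions
  (defaults 0.45/0.35/0.20), exponential relaxation to class-specific
  retained plateaus (0.95/0.5/0.02) with noise SD 0.03.
* `simulateDoseResponse()` — `a·x/(b + x)` at doses 1–10 displacements
  (defaults a = 400 amol/cell, b = 3), times lognormal noise.

These emulate the *statistical structure* the estimators rely on, not real
microscopy: there is no cell morphology, no PSF beyond a Gaussian, no
luciferase reaction kinetics, no ATP degradation, and no motion. Passing the
recovery benchmarks therefore demonstrates correctness of the estimators
under their stated models — not robustness to every artifact of real
recordings.

# Numerical choices and problem sizes

* All nonlinear fits use Levenberg–Marquardt (minpack.lm) with positivity
  bounds where the model requires them; linear fits use ordinary least
  squares.
* Mass conservation of the diffusion kernel is checked by trapezoidal
  integration over |x| ≤ 10·√(4Dt) on 4001 points.
* The recovery benchmarks exercised by the tests and the acceptance script
  use: 100 transients (SNR 20), 50 fields (responder probability 0.5,
  effect 8 SD), 200 concentration profiles (CV 5%), one benchmark stack
  (20 puncta, 10 events, 5 fades, SNR 5) plus 5 pure-noise stacks, a
  200-trace injury cohort with three 300-trace cohorts at increasing noise,
  and 50 replicate dose-response data sets. These sizes give stable medians
  while keeping a full run to a few seconds.
* Estimator accuracy on stochastic benchmarks is summarized by the median
  over replicates (median recovered value or median relative error), which
  is insensitive to the occasional hard draw.

# Known limitations

* The plane-source geometry is one-dimensional; real pericellular diffusion
  has curvature, boundaries and convection. The fitted σ inherits that
  idealization, and the per-cell amount additionally inherits the supplied
  effective area.
* Event detection assumes stationary puncta; cells that migrate or deform
  during the recording violate the fixed-ROI assumption.
* The calibration model assumes power-law reporter response; reagent
  consumption and luciferase diffusion are not modelled.
* Injury classification depends on the background floor estimate; without a
  cell-free region the floor defaults to 0, which overstates the retained
  fraction when autofluorescence is present.
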