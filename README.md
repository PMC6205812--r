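# MechanoATP

Quantitative analysis of mechanically stimulated ATP release from bone
cells.

When an osteoblast or osteocyte is mechanically deformed — by a
micropipette, by fluid shear — it releases ATP within seconds, triggering
calcium responses in neighboring cells. The size of that release reflects a
balance between transient membrane injury and vesicle-mediated membrane
repair. MechanoATP packages the analysis chain such experiments need, for
cell biologists and biophysicists working with single-cell imaging and
plate-reader data:

- **Calcium transients** (Fura-2 f340/f380 ratio traces): amplitude,
  10–90% activation time t<sub>act</sub>, exponential decay constant
  τ<sub>decay</sub>, activation rate = amplitude / t<sub>act</sub>, and the
  percentage of neighboring cells responding (secondary responsiveness).
- **ATP quantification**: log-log luciferin/luciferase calibration
  (signal ↔ [ATP]), and estimation of the amount released by a single cell
  by fitting pericellular concentration profiles with the instantaneous
  plane-source diffusion law

  c(x, t) = σ / (2·√(πDt)) · exp(−x² / 4Dt),

  with σ the areal source strength (amol/µm²), D = 330 µm²/s
  (3.3×10⁻⁶ cm²/s) by default, and the released amount
  M = σ · effective area. Bulk release per cell, percent of cellular ATP
  content, saturating dose–response fits y = a·x/(b + x), and regression
  summaries round out the module.
- **Vesicular exocytosis**: Laplacian-of-Gaussian detection of
  quinacrine-positive puncta, vesicular density (vesicles/µm²), and release
  events called as abrupt fluorescence losses via temporal reversal of the
  stack — vesicles drifting out of focus are rejected by a
  transition-completeness test.
- **Membrane injury**: classification of dye-leakage traces into minor /
  intermediate / severe injury (mIn/iIn/sIn) by retained fluorescence
  fraction, dye-uptake and LDH-leakage percentages, and bracketing of the
  membrane lesion radius from tracer permeability using minimal molecular
  radii R = 0.066·MW^(1/3) nm.
- **Synthetic data** generators for every input above, each returning a
  ground-truth sidecar, so the whole pipeline is testable end to end with
  known answers.

Data containers are S4 classes (`FluorescenceTrace`, `FieldRecording`,
`ImageStack`, `ConcentrationProfile`, ...) with validity checks, accessors
and `show()` methods; I/O covers tidy trace CSVs with YAML sidecars,
multi-page float TIFF stacks, dye tables, and JSON result records.

## Worked example

```r
library(MechanoATP)

## a noisy synthetic calcium transient, then recover its parameters
sim <- simulateTransient(seed = 42, snr = 20)
characterizeTransient(sim$trace, estimateBaseline(sim$trace))
#> TransientParams 'sim'
#>   baseline  1.004   amplitude 0.4954
#>   tPeak     14 s tAct      2.036 s tauDecay 21.74 s
#>   activation rate 0.2433 /s  decay-fit R2 0.966

## single-cell ATP release from a pericellular concentration profile
prof <- simulateSourceProfiles(sigma = 0.05, noiseCv = 0.05,
                               seed = 42)$profiles[[1]]
fitSourceAmount(prof, effectiveArea = 400)
#> SourceEstimate (linear):
#>   sigma 0.05096 amol/um^2, M 20.38 amol (area 400 um^2)
#>   D 330 um^2/s, t0 offset 0 s, R2 0.9787

## membrane lesion radius bracketed by tracer permeability
lesionRadiusBracket(defaultDyeTable())
#> LesionBracket: [0.637, 1.42) nm over 5 dyes
molecularRadius(507)          # ATP: 0.526 nm, small enough to escape
#> [1] 0.5262756

## fraction of the vesicular pool released over 100 s
percentPoolReleased(5e-3, 70e-3)
#> [1] 7.142857
```

The transient recovery reads: the true generating values were amplitude
0.5, t<sub>act</sub> ≈ 2.07 s, τ = 20 s; at SNR 20 the estimates land
within a few percent. The source fit recovers the generating σ = 0.05
amol/µm² to ~2% on this draw and converts it, for a 400 µm² release area,
to ~20 amol of ATP — the attomole scale characteristic of single-cell
release. The lesion bracket says the permeability pattern of the default
tracer panel (trypan blue in, 10 kDa dextran out) requires a lesion of
0.64–1.42 nm radius, comfortably above the 0.53 nm minimal radius of ATP.

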