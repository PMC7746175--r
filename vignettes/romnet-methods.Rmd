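---
title: "romnet: methods, parameters and design choices"
author: "romnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{romnet: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romnet)
```

# Overview

`romnet` implements an analysis pipeline for active cervical
range-of-motion (aROM) assessments in whiplash-associated disorders:
oscillatory neck-angle traces are segmented into repetitions and
summarised per movement; the six normalized ROMs are condensed into the
NFHAS polygon-area score; 18 kinematic predictors feed a feed-forward
regression network trained with Levenberg–Marquardt and selected by
Monte-Carlo cross-validation; and a held-out evaluation suite reports
regression R, quadrant agreement and paired pre/post tables. A synthetic
cohort generator with known ground truth makes every stage testable.

This vignette is the package's own account of the methods: the model and
its assumptions, the tunable parameters with units and defaults, what the
generator emulates (and deliberately does not), and the numerical choices
made where the design was genuinely open.

# Kinematic summaries

## Repetition segmentation

A recording is one movement pair performed as a self-paced oscillation
for 45 s. `segmentRepetitions()` detects alternating angle extrema by
reversal filtering: a turning point is kept only when the swing from the
previous kept extremum reaches `prominence` (degrees) and the spacing
reaches `minHalfPeriod` (seconds). One repetition is one excursion to the
peak angle and back: the window between the surrounding opposite
extrema, with the trace ends serving as boundaries for the first and last
cycle. Per repetition:

* `rom` — max minus min angle within the window (degrees). ROM is the
  *directional excursion* of the movement; whether a device reports
  per-direction ROM from a neutral reference or as half of a pair's
  excursion is a convention, and this package fixes the former and
  applies it consistently, generator included.
* `peak_speed` — the largest |finite-difference angular velocity|
  between window start and the peak sample (deg/s). Velocity uses
  central differences, one-sided at the endpoints.
* `peak_angle`, `time_to_peak` — support the alternative speed summary.

Defaults `prominence = 5`°, `minHalfPeriod = 0.3` s were chosen as the
smallest values that ignore sensor-scale wiggle (a few degrees) while
keeping genuinely slow, small movements of severely limited patients; on
a pure sinusoid of amplitude A and period T the segmentation recovers
`duration/T` repetitions with ROM `2A` and peak speed `2πA/T` to
discretization accuracy (the test suite asserts both).

## Movement summary

`summarizeMovement()` averages repetitions: `mean_rom`, `speed_to_peak`
(mean of per-repetition peak speeds), `cv = 100·sd(rom)/mean(rom)` and
`rom_normalized = 100·mean_rom/normative`. Two decisions:

* **Speed definition.** "Speed to peak" is not uniquely defined by the
  assessment protocol. The default is the per-repetition peak absolute
  angular velocity on the way to the peak, averaged over repetitions —
  the quantity an inertial device measures most directly. The
  alternative (peak angle ÷ time to peak, a mean slope) is available via
  `speedMethod = "peak_over_time"`.
* **Single repetition.** With one repetition the sample SD is undefined;
  `cv` is set to 0 and a message emitted, because downstream z-scoring
  cannot absorb missing values. Assessments with *zero* complete
  repetitions are an error.

The normative ROM table is user configuration (`normativeROM(path)`); no
normative table accompanies the assessment protocol, so the package
ships a default (`inst/extdata/normative_rom_default.csv`) with adult
reference values in the range reported across cervical goniometry
literature, declining 5% per decade after the twenties. It is a package
default for the synthetic pipeline, not a published normative dataset.

# The NFHAS score

`nfhasScore()` combines the six directional normalized ROMs. Opposing
directions are averaged per axis (flexion-extension, lateral bending,
rotation), the three axis values are placed as vertices on mutually
orthogonal axes, the triangle sides are Euclidean vertex distances and
the area follows Heron's formula; the score is 100 times the ratio to the
ideal polygon (every ROM at 100%).

**Geometry choice.** The scoring formula names exactly three sides and
one area, and the score "combines the three normalized main ROMs", so
the default geometry is a single triangle on three orthogonal axes. The
originating publication of the score is not explicit about whether its
polygon had three or six vertices, nor whether opposing directions were
combined by mean or sum; both alternatives are implemented
(`geometry = "octant"` sums the eight octant faces of six directional
vertices on ±axes; `combine = "sum"`). All variants satisfy the two
structural properties the score's definition forces: the ideal case
scores exactly 100, and scaling all ROMs by k scales the score by k²
(both property-tested).

Scores above 100 are possible when a patient exceeds normative ROM
(hypermobility) and are not clipped; staging treats them as type 1.
Degenerate inputs are well-defined: a zero axis collapses the triangle
to a right triangle on the remaining axes; all-zero input scores 0. In
`heronArea()` a radicand driven slightly negative by floating-point
cancellation is clamped to 0; a genuine triangle-inequality violation
(beyond a 1e-9 relative slack) is an error.

**Severity staging.** `stageSeverity()` defaults to fixed thresholds
80/60/40/20 — five equal-width bands of the score range, type 1 highest —
because the k-means clustering that originally established "5 groups" is
not reproducible without the original cohort. One-dimensional k-means
(k = 5, fixed seed, `nstart = 10`, centroids sorted descending) is
available via `method = "kmeans"`; with fewer than 5 distinct scores it
falls back to thresholds with a warning.

# Predictors, outliers and the target

The 18 predictors are `(rom_normalized, cv, speed_to_peak)` × six
movements, in the fixed order of `featureNames()`. Exclusion uses the
3-scaled-MAD rule per predictor across the cohort: `|x − median| >
3 · 1.4826 · MAD` (1.4826 is the Gaussian-consistency constant, the
default of `stats::mad()`); a patient with *any* flagged predictor is
dropped, follow-up record included. When MAD = 0 (near-constant
predictor) the rule alone would flag either nothing or everything;
the package flags a value only when it deviates at all *and* a secondary
scaled-IQR criterion (`3·IQR/1.349`) also flags it, so one wild value
among constants is caught while constant vectors stay clean.

z-scoring uses the sample SD (n−1) and returns its parameters; inside
cross-validation they are fitted on the training side only and reused on
validation. The original analysis is silent on this; fitting inside the
split is the leakage-free choice and is acknowledged as possibly stricter
than the original. The target `NFHAS(followup) − NFHAS(baseline)` stays
on its native percentage-point scale (it is *not* z-scored): validation
MSEs of a few hundred on this scale are consistent with the reported
headline errors, which a standardized target could not produce.

# Network and training

`netModel()` builds `18 – hidden – 1` networks, tanh hidden activation,
linear output — the de-facto standard pairing for Levenberg–Marquardt
regression toolboxes — with `identity` activation available (used by the
OLS-equivalence tests). Initialization is uniform in [−0.5, 0.5] from an
explicit seed (Nguyen–Widrow offered as an option); the epoch budget and
stopping rules of the original training are unstated, so all are
documented configuration.

`trainLM()` iterates the damped Gauss–Newton step
`(JᵀJ + λI) δ = Jᵀe` with the analytic per-sample Jacobian
(`netJacobian()`, verified against central finite differences): accept
and `λ ← λ·0.1` on MSE decrease, reject and `λ ← λ·10` otherwise; stop
on `maxEpochs` (default 1000), small error gradient (`gradTol = 1e-7` on
max |dMSE/dθ|), or `λ > 1e10`. A singular system raises λ and retries —
rank deficiency is never fatal. The accepted-step MSE history is strictly
decreasing by construction. With identity activation and vanishing λ one
step reproduces the ordinary-least-squares solution exactly; both
properties are tested.

# Model selection

`enumerateArchitectures(17, 2)` covers all single-layer widths 1..17 and
every two-layer split with at least one neuron per layer and total ≤ 17 —
153 candidates, ordered by total neurons, then layers, then first-layer
width. The search protocol's "one neuron added or relocated at every
epoch" walk is interpreted as exhaustive coverage of this bounded space,
since the reported results compare MSE *across* architectures; a greedy
walk would be a strict subset and can be emulated by passing a candidate
subset.

`monteCarloCV()` draws, per repeat, a fresh random 70/30 patient split
and a fresh initialization, fits z-scoring (and optionally PCA) on the
70%, trains, and records validation MSE; 10 repeats by default. The
repeats are summarised as mean and Student-t 95% interval
(`mean ± t(0.975, n−1)·sd/√n`) — the interval construction is not stated
in the original and Student-t on 10 repeats is the standard choice.
Splits are *not* shared across architectures (unpaired comparison; the
original is silent). `selectArchitecture()` takes the argmin of the mean
MSE, breaking ties toward fewer total neurons, then fewer layers.
Reproducibility: every (architecture, repeat) pair derives its own RNG
substream from the search seed, so results are independent of evaluation
order.

**PCA variant.** `pcaTransform()` rotates the z-scored predictors with
all components retained (removal fraction 0), matching the protocol of
"uncorrelated components, nothing removed"; components beyond numerical
rank are dropped with a warning. Sign convention: each component's
largest-magnitude loading is positive. At removal fraction 0 the
transform is a pure rotation, so for a linear model the attainable fit is
unchanged (tested); any performance difference for tanh networks comes
from the interaction of the rotation with initialization and the
nonlinearity.

# Evaluation

`fitPerformanceRegression()` regresses real change on predicted change;
R is the Pearson correlation (identical in magnitude to the simple
regression's multiple R, sign preserved). `assignQuadrants()`
cross-classifies real vs predicted direction; **zero change counts as
"not improve"** (the boundary is undefined in the source convention; zero
is not an improvement, and occurrences are logged). `pairedTTest()` is
computed from the closed form and cross-checked against `t.test()` to
1e-9 in the suite; the primary sign convention is post − pre (positive =
increase after rehabilitation) with the pre − post mean reported
alongside, because published pre-vs-post tables are sign-inconsistent
across groups. No multiple-testing correction is applied across the table
families (matching the per-test α = 0.05 convention); a Holm-adjusted
column is emitted as a clearly-marked extra. The error histogram defaults
to 20 equal-width bins; explicit shared edges support train/validation
overlays.

# The synthetic cohort generator

The generator defines the study conditions for all testing:

* **Severity profiles** (`severityProfiles()`): five types spanning
  100% → 30% of young-adult normative ROM in equal steps; speed scaled
  1.00/0.85/0.70/0.55/0.40 with rotation (80 deg/s at type 1) >
  flexion-extension (60) > lateral bending (45); ROM CV means
  4/6/8/10/18% — rising gradually then jumping at type 5, reflecting the
  reported pattern that movement inconsistency spikes in the severest
  group. Numeric per-type means were never published; these profiles are
  calibrated qualitatively to the published ordering claims and are
  configuration, not constants (`validateProfiles()` enforces the
  orderings for any user profile set).
* **Type proportions** 3.69/16.82/24.67/31.23/23.56% (renormalized to
  sum exactly to 1; as printed they sum to 99.97%). **Demographics**: age
  37 ± 12.88 y (truncated at 18), 55.1% female, height 1.67 ± 0.09 m,
  mass 72.41 ± 15.47 kg. ROM draws are scaled by the age-specific
  normative so normalized ROM has the same severity meaning at every age.
* **Traces** (`generateTrace()`): quasi-sinusoidal cycles running
  neutral → peak → neutral; per-cycle amplitudes are lognormal with the
  profile's mean ROM and CV, periods set so peak speed matches the
  profile (±10% uniform jitter), amplitude switches at the neutral touch
  points keep the signal continuous. Feigned effort is emulated only as
  inflated CV — no biomechanical or musculoskeletal simulation.
* **Ground truth** (`recoveryModelSpec()`): NFHAS change = intercept
  (default +8 points) + linear combination of the 18 cohort-z-scored
  predictors + Gaussian noise, saturated smoothly (tanh cap) so the
  follow-up score stays in [0, 100]. Default weights: −2 per normalized
  ROM (more limited patients have the most room to improve), −0.6 per CV
  (inconsistent movement predicts poorer recovery), +0.8 per speed.
  The follow-up record is built by scaling baseline ROMs by
  √(NFHAS₂/NFHAS₁) — exact by the score's k² law — with speed scaling
  alongside ROM and CV inversely.
* **Noise calibration.** The default `noise_sd = 6` NFHAS points was
  fixed once so that a trained network's held-out correlation with the
  real change lands near 0.5 at default settings — the
  moderate-predictability regime the analysis targets. The deterministic
  signal's SD at defaults is ≈ 4.6 points.
* **Reproducibility.** Each patient draws from an RNG substream derived
  from (seed, patient index) by a Lehmer-style multiply–add modulo
  2³¹−1 (exact in doubles), so cohorts are reproducible independent of
  generation order; truncated-normal draws consume a fixed number of
  uniforms via the inverse CDF so streams never desynchronize.

**What passing tests do and do not show.** The generator produces
unimodal within-type kinematics, exact follow-up consistency with the
ground-truth change, and noise that is Gaussian and independent across
patients. Real assessments have none of these guarantees: measurement
artifacts, treatment heterogeneity, feigned effort and unmodelled
psychosocial factors all act on the target. Parameter recovery therefore
demonstrates that the pipeline measures signal rather than leakage — the
low-noise cohort must reach held-out R ≥ 0.9 and a noise-dominated
cohort must stay below R < 0.2 — but says nothing about predictive
performance on real patients. The noise-dominated control shrinks the
recovery coefficients (×0.2, with noise 15) rather than inflating noise
alone, because extreme noise drives most follow-ups into the [0, 100]
saturation bounds, where the capped change becomes a deterministic — and
hence learnable — function of the baseline score, which would defeat the
purpose of a negative control.

A known interaction: the 3-scaled-MAD rule applied to a five-type
severity *mixture* flags the extreme tail of the pooled distribution —
around 10–15% of synthetic patients at defaults — whereas the original
cohort reportedly contained few outliers. This is a property of the rule
on mixture distributions, not a bug; narrower or wider profile
dispersions move this rate.

# Problem sizes and numerical tolerances used in testing

The test suite exercises parameter recovery at the full cohort size
n = 1082 with a reduced search grid (5 candidates × 5 repeats, 60-epoch
budget, 150 epochs for the final fit) — the grid reduction trades
exhaustiveness for a search that still selects among meaningfully
different capacities. Property suites use seeded random families
(≥ 100 draws for geometry, 1000 for the outlier rule); closed-form
comparisons use 1e-9 relative tolerance, Jacobian-vs-finite-difference
1e-6, and serialization round-trips 1e-12. Pipeline determinism is
asserted at the byte level on all written artifacts; no artifact embeds
a timestamp for exactly this reason.

# Known limitations

* The NFHAS geometry and staging reproduce the *definitions*, not the
  original cluster centroids; absolute staging of real patients may
  differ from the originating system.
* `speed_to_peak` is one of two defensible definitions (both provided).
* The generator's recovery model is linear-with-saturation by design;
  genuinely nonlinear recovery dynamics would favour larger
  architectures than the synthetic benchmarks select.
* Reported headline numbers of the motivating clinical analysis (mean
  MSE ≈ 290, held-out R ≈ 0.5, quadrant percentages) depend on the
  private cohort and are not reproduction targets; the package
  reproduces procedures, and its synthetic defaults are calibrated only
  to land in the same qualitative regime.
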