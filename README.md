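# romnet

Cervical range-of-motion kinematics, polygon-area mobility scoring and
neural-network prediction of rehabilitation outcome.

## The problem

After a whiplash-associated disorder (WAD), clinicians track recovery
through the active cervical range of motion (aROM). A standardized
assessment records, for each of the three movement pairs
(flexion/extension, left/right lateral bending, left/right rotation), a
45-second self-paced oscillation of the neck angle. From each recording
three summaries are extracted per movement: the **normalized ROM**
(percent of the age-appropriate normative range), the **ROM coefficient
of variation** across repetitions (a movement-consistency measure), and
the **speed to peak** (deg/s). Global mobility is condensed into a single
percentage, the **NFHAS** (Neck Functional Holistic Analysis Score): the
three axis ROMs are placed as vertices on orthogonal axes, the polygon
they span is measured with Heron's formula

&nbsp;&nbsp;&nbsp;&nbsp;*A* = √( *s*(*s*−*a*)(*s*−*b*)(*s*−*c*) ), *s* = (*a*+*b*+*c*)/2,

and the score is 100 · *A* / *A*₁₀₀, the area relative to the ideal
polygon with every normalized ROM at 100%. Severity is staged into five
NFHAS types (1 = complete ROM, 5 = severe limitation).

The question this package operationalizes: **can the 18 baseline
kinematic predictors** — (normalized ROM, ROM CV, speed to peak) × six
movements — **predict the change in NFHAS over rehabilitation?** The
predictor is a feed-forward regression network (tanh hidden units, linear
output) trained with a from-scratch **Levenberg–Marquardt** optimizer,
its architecture chosen by **Monte-Carlo cross-validation** (repeated
random 70/30 splits, ≤ 17 hidden neurons, ≤ 2 hidden layers, 10 repeats,
mean validation MSE with a Student-t 95% interval), with an optional PCA
pre-processing variant. Patients with any predictor beyond 3 scaled
median absolute deviations from its cohort median are excluded before
modelling.

Because the clinical cohort is private, the package ships a
**synthetic-cohort generator** that emulates its structure — severity
profiles with decreasing ROM/speed and increasing CV across NFHAS types,
rotation faster than flexion-extension faster than lateral bending, the
published baseline type proportions and demographics — together with a
known ground-truth recovery model, so the entire pipeline is testable by
parameter recovery.

## Worked example

```r
library(romnet)

cfg    <- syntheticConfig(nPatients = 300, seed = 42)
cohort <- generateCohort(cfg)
cohort
#> NeckCohort: 300 patients x 2 time points (24 assay rows)
#>   baseline NFHAS: median 24.9 [8.0, 110.6]

kept <- filterOutlierPatients(cohort)
#> outlier filtering: excluding 41 of 300 patients
bl <- baselineRecords(kept)
X  <- rawFeatures(bl)                        # n x 18 raw predictors
y  <- buildTarget(bl, followupRecords(kept)) # NFHAS difference

search <- searchArchitectures(X, y, candidates = list(4L, 8L, 10L),
                              nRepeats = 5, seed = 1, maxEpochs = 60)
print(search$report, row.names = FALSE)
#>  architecture layers neurons  mean_mse   ci_low   ci_high repeats
#>             4      1       4  46.20332 34.21239  58.19425       5
#>             8      1       8  89.39662 56.04193 122.75131       5
#>            10      1      10 159.45603 48.70439 270.20767       5

set.seed(7)
idx  <- sample(seq_len(nrow(X)), round(0.7 * nrow(X)))
zf   <- zscoreFitMatrix(X[idx, ])            # fitted on the 70% only
fit  <- trainLM(netModel(18, search$best, seed = 2), zf$values, y[idx],
                maxEpochs = 150)
zVal <- applyZscore(X[-idx, ], zf$center, zf$scale)
report <- evaluatePredictions(
  setNames(forwardPass(fit$model, zVal), rownames(X)[-idx]),
  y[-idx], cohort = kept)
report
#> EvaluationReport (n = 78 held-out patients)
#>   R = 0.455, MSE = 47.57, real ~ 1.667 + 0.757 * predicted
#>   quadrants (real predicted): 1 1: 82.1%, 1 -1: 3.8%, -1 1: 6.4%, -1 -1: 7.7%
#>   paired pre/post tables for 4 quadrant groups
```

Reading the output: the Monte-Carlo search prefers the small 18-4-1
network on this 259-patient cohort (larger nets overfit the noisy
target); the held-out correlation between predicted and real NFHAS change
is R = 0.46 — the moderate-predictability regime the generator's default
noise is calibrated to; 82% of held-out patients improved and were
predicted to improve ("1 1"), while 6% deteriorated despite a predicted
improvement ("-1 1"). `report@tables` holds the per-quadrant paired
pre/post t-tests of ROM, speed and ROM CV per movement.

The single call

```r
runPipeline(pipelineConfig(nPatients = 300, seed = 42), "out/")
```

performs the same steps end to end (simulate → features → nfhas → search
→ train → evaluate), writing every artifact as CSV/JSON plus a run
manifest; a rerun with the same configuration is byte-identical.

## Vignette

`vignettes/romnet-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, and the numerical design choices.
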