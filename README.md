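# srmap

Model-based analysis of anticipatory fMRI responses to learned visual
sequences, asking whether activity in retinotopic visual cortex and
hippocampus is organized like a **successor representation (SR)** — a
predictive map in which each state encodes its temporally discounted future
states.

Participants learn a fixed four-dot sequence A-B-C-D on an 8-location
circular layout. On occasional *partial* trials only one item is shown.
The SR predicts graded, forward-only anticipation at the omitted locations:
with transition matrix `T` of the chain and discount `γ ∈ [0, 1]`,

```
M = (I − γT)⁻¹,   M[i, j] = γ^(j−i)  for j ≥ i,  0 otherwise,
```

so showing B should activate C more than D and not activate A. The package
fits this SR model against a non-directional co-occurrence model (CO:
constant off-diagonal `ω`) and a no-anticipation null (H0) on each
subject's control-subtracted 4×4 partial-trial activity profile, comparing
them by RMSE and BIC. A hippocampal pathway decodes the eight locations
from multivoxel patterns (L2 logistic regression, C = 1) and contrasts
classifier evidence at successor versus predecessor locations; a localizer
coactivation ("tuning") analysis distinguishes temporal-distance from
spatial-distance codes, which the constrained sequence geometry decouples
(the temporally adjacent pair A-B is spatially maximal).

Because the analyses are exercised on **synthetic cohorts with known ground
truth** (a seeded BOLD simulator with retinotopic V1 subpopulations,
tunable hippocampal pattern coactivation, canonical HRF at TR = 1.5 s, and
white noise), every stage is testable by parameter and model recovery
without any data download. Real preprocessed series can be supplied as
delimited tables or NIfTI plus event tables.

## Worked example

The numbered scripts under `analysis/` run the full workflow; the core one
is the V1 model comparison on a 35-subject SR cohort (true γ = 0.3):

```sh
Rscript analysis/01_design.R
Rscript analysis/03_v1_model_comparison.R
```

prints

```
Successor vs predecessor activity: 0.190 vs 0.003 beta units;
  paired t(34) = 24.59, p = 3.1e-23; Wilcoxon V = 630, p = 2.6e-07
Group mean activity at successor lags +1..+3: 0.305, 0.096, 0.035; exponential decay gamma = 0.322
Per-subject SR fits: gamma = 0.305 +/- 0.040 (mean +/- sd, n = 35)
Group mean RMSE: SR 0.0674, CO 0.1260, H0 0.1530
Group mean BIC: SR -81.4, CO -61.1, H0 -57.5
Winning model (lowest group-mean BIC): SR
```

Read: anticipatory activity appears at future sequence locations but not at
past ones; it decays with temporal distance (the fitted per-subject
discount recovers the generating γ = 0.3); and the SR model beats both the
co-occurrence and null accounts for essentially every subject.
`analysis/04_hippocampus_decoding.R` runs the decoding pathway (localizer
accuracy against 12.5% chance, successor/predecessor evidence contrast,
time-resolved evidence), and `analysis/05_tuning.R` shows that cohorts
generated with temporal, spatial, or no hippocampal coactivation are each
identified by the tuning-model comparison. Outputs land in `results/` as
TSV/JSON.

In code, the same pathway is three calls:

```r
library(srmap)
cohort   <- make_cohort(35, ground_truth(gamma = 0.3), seed = 1)
profiles <- cohort_v1_profiles(cohort)   # simulate → GLM → control-subtract
model_comparison(profiles)$winner        # "SR"
```

## Layout

```
R/                  implementation (geometry/design, simulator, HRF, GLM,
                    SR models, decoding, tuning, group stats, I/O, pipeline)
analysis/           numbered workflow drivers writing to results/
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, simulator, design choices
```
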