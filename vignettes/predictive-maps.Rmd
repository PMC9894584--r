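---
title: "Predictive maps in visual cortex and hippocampus: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive maps in visual cortex and hippocampus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmap)
```

## The scientific question

After repeated exposure to a fixed visual sequence of four dots (A-B-C-D),
does showing a single item evoke activity at the *omitted* locations — and
if so, is that anticipatory activity organized like a successor
representation (SR)? The SR hypothesis predicts that a state is represented
in terms of its temporally discounted future states: presenting B should
activate C (one step ahead) more than D (two steps ahead) and should not
activate the predecessor A. The alternative co-occurrence (CO) account —
pattern-completion of everything associated — predicts equal reactivation of
all sequence mates, past and future. A null account (H0) predicts no
anticipatory activity at all.

`srmap` implements this analysis end to end: the constrained stimulus and
session design, a synthetic BOLD cohort generator with known ground truth,
GLM estimation of location-specific responses, the SR/CO/H0 model
comparison, hippocampal multivoxel decoding with successor/predecessor
evidence contrasts, and a localizer coactivation ("tuning") comparison that
distinguishes temporal from spatial codes.

## The models

With states A-D and the one-step transition matrix `T` of the chain
(`T[A,B] = T[B,C] = T[C,D] = 1`, D terminal), the successor matrix is

$$M = (I - \gamma T)^{-1}, \qquad \gamma \in [0, 1],$$

so for the terminal chain `M[i, j]` equals `gamma^(j - i)` for `j >= i` and
0 below the diagonal. `gamma` is the discount factor or predictive horizon:
values near 0 mean a steep decay of anticipation into the future; 1 means no
decay. The three models predict the 4x4 matrix of partial-trial responses
(rows: shown item; columns: probed sequence location):

* **SR** — row `s` of `a * M(gamma)`: graded, forward-only anticipation;
* **CO** — diagonal `a`, all off-diagonal cells `a * omega`:
  non-directional, ungraded;
* **H0** — diagonal `a`, off-diagonal 0.

The diagonal carries the bottom-up response to the shown dot in all three
models, so the models differ only in their account of the anticipatory
cells. Each model has a multiplicative scale `a` shared across all 16 cells,
putting predictions on the scale of GLM betas (how the original analysis
scaled its predictions is not printed; the multiplicative reading keeps H0
at one parameter, preserving "H0 has fewer parameters" in the BIC). An
additive intercept is deliberately not included; control subtraction already
removes per-condition offsets. `omega` may be negative, since predecessor
*suppression* (below-baseline activity at past locations) is empirically
meaningful.

Fits minimize the RMSE over all 16 cells — the stimulated diagonal is
included because the models make a prediction for it. The SR fit uses a
deterministic grid on `gamma` (step 0.01) with `a` solved in closed form at
each point, then local refinement; CO and H0 have exact closed forms.
Determinism was preferred over stochastic optimizers because every
landscape here is one-dimensional and smooth. Model comparison is by
group-mean BIC, computed as `n log(RSS/n) + k log(n)` under Gaussian errors
(the criterion is named without a formula in the original report; this is
the standard least-squares form, and only differences between models on the
same data matter).

## Geometry and design

Eight dot locations sit on a 7-dva circle at angles 22.5°, 67.5°, ...,
337.5°, measured clockwise from the vertical meridian (the clockwise
convention matches the construction "the second dot 180° clockwise from the
start, the third 90° clockwise from the second"; whether "clockwise" is
screen-relative is not decidable from the text, and any consistent choice
yields the same eight sequences up to relabelling). Each of the 8 locations
starts one sequence; each sequence visits every quadrant once, and no two
sequence locations are 45° neighbours. The resulting chord-distance multiset
among sequence locations is {9.9 (x4), 14.0 (x2)} dva, and crucially the
temporally adjacent pair A-B is spatially maximal (14.0 dva) — time and
space are decoupled by construction, which is what lets the tuning analysis
discriminate temporal from spatial codes.

Sessions have 3 runs x 192 trials: 128 full-sequence trials (451 ms: four
100 ms dots, 17 ms ISIs; 52 per run carry a delayed 170 ms last-dot ISI)
and 64 partial trials (100 ms), 16 per sequence item. Partial trials are
always flanked by full trials; the schedule is sampled uniformly over all
orders satisfying that constraint by placing the 64 partial trials into 64
of the 127 internal gaps between consecutive full trials (a constructive
sampler — unlike rejection shuffling it cannot fail and is exactly
uniform). ITIs are drawn from an exponential with minimum 2 s, truncated at
10.9 s, with the scale root-found so the truncated mean is 3.72 s (the
source states the mean but not the rate; the feasible mean range is
(minimum, midpoint)). Onsets accumulate trial duration plus ITI from t = 0,
giving runs of about 13 minutes.

The localizer flashes each dot for 13.5 s blocks, 8 repetitions per
location, 15 s rest after each cycle of eight blocks (984 s ≈ 16.4 min,
matching the stated ~16 min — the alternative reading, a rest after every
block, gives ~30 min and was rejected). Each location occurs exactly once
as a cycle-initial block; cycle 1's first block follows the pre-run
baseline, which we count as the eighth post-rest slot since only seven
blocks can follow an interior rest.

## The synthetic cohort generator

`ground_truth()` fixes the generative conditions; `make_cohort()` assigns
each subject one of the eight sequences, counterbalanced in frequency, and
a deterministic per-subject seed.

**V1.** Eight retinotopic subpopulations (default 8 voxels each). Every
trial places one impulse per driven location at trial onset: full trials
drive the four sequence locations at `stimulus_amplitude` (1 beta unit);
partial trials drive the shown location, plus anticipatory amplitudes at
the omitted sequence locations given by the generative model (row of
`M(gamma)` for SR, constant `omega` for CO, zeros for H0). Bottom-up drive
bleeds to neighbouring locations with a Gaussian in chord distance (scale 1
dva, making 5.4-dva neighbour bleed ~5e-7 — sharp retinotopic tuning with
minimal spread). Impulses are convolved with a canonical double-gamma HRF
(peak delay 6, undershoot delay 16, ratio 1/6, unit peak, support truncated
at 32 s), sampled at TR = 1.5 s, plus white Gaussian noise (SD 2 per voxel
per volume, i.e. single-event SNR 0.5 — a moderate event-related level).
Within-trial dot asynchrony (≤ 0.35 s) is collapsed to the trial onset in
both the simulator and the GLM; at HRF timescales this is negligible and it
makes noiseless GLM recovery exact, which the test-suite oracles exploit.
The GLM analysis pathway consequently uses the same double-gamma basis as
the generator; the single-gamma basis remains available for standalone
designs.

**Hippocampus.** Each location gets a random Gaussian voxel pattern
(default 64 voxels); the pattern evoked by a sequence location is a mixture
of its own base pattern and its sequence-mates', with mixing weights that
decay linearly with absolute sequence lag (temporal tuning, default
intercept 0.6, slope -0.15), with chord distance (spatial tuning, defaults
spanning the same 0.15-0.45 weight range at the realized 9.9/14.0 dva
distances), or not at all ("none"). Main-task trials drive the patterns of
their driven locations exactly as in V1 (amplitude 0.03), localizer blocks
drive them as 13.5 s boxcars.

**Calibration.** Where the source gives no effect-size anchor in beta
units, the defaults were set once, before the acceptance checks were
frozen, so that (i) the group successor>predecessor V1 test at n = 35 is
clearly in the reported direction, (ii) gamma recovery and SR/CO/H0 model
selection succeed at the study's sample size, and (iii) the three tuning
conditions are identifiable. The hippocampal operating point is
deliberately weak: raising the hippocampal amplitude makes the localizer
decoder sharper, and the softmax then compresses linear coactivation into a
geometric-looking profile (misidentified as SR) while the main-task
contrast does not strengthen. At the chosen point the cohort-level
successor-minus-predecessor evidence contrast is very small — mirroring how
small the reported hippocampal effect is in the real data — so the suite
demonstrates its recovery under the forward-skew isolation conditions
described under Known limitations, asserting the direction at n = 35.

**What the generator does not emulate:** head motion, physiological and
temporally autocorrelated noise (an AR(1) switch was considered and left
out of the defaults), scanner drift, anatomical geometry, and
hemodynamic variability across regions. Passing tests therefore demonstrate
that the analysis code recovers known ground truth through an idealized
linear BOLD model — not that the pipeline is robust to every artifact of
real fMRI.

## Analysis pathways

**V1 GLM.** Per run: one regressor per partial type plus one for full
trials, impulses convolved with the HRF basis and sampled at volume times;
OLS per voxel; betas averaged over runs (unweighted); voxels averaged
within each location ROI; the four control-location ROI means subtracted
per condition. Nuisance regressors pass through unconvolved; none are used
for synthetic data (no motion is simulated). On the localizer, one-vs-rest
contrast z maps (t mapped through the normal quantile, computed on the
small tail for stability) feed the preregistered voxel selection: top 25
per location, voxels selective for more than one location removed
everywhere ("selective" operationalized as membership in more than one
top-25 list, the closest literal reading), all sets trimmed to the minimum
size. The acceptance cohorts reuse the simulator's known voxel labels
rather than re-running the localizer selection per subject, which is
exercised separately; with the default geometry both give the same sets.

**Decoding.** Voxel time courses are Savitzky-Golay filtered (window 5 TRs,
order 3; endpoint handling by the filter's own least-squares end rows) and
z-scored per voxel per run — standard MVPA practice that removes run
offsets, since the scope of "normalized to z-scores" is not stated. Trial
features average volumes 3-13.5 s (localizer) or 3-6 s (main task) after
onset, inclusive. The decoder is multinomial logistic regression with L2
penalty at inverse strength C = 1 (ridge `glmnet` at lambda = 1/(nC),
unstandardized — the same objective as the common scikit-learn
parameterization). Localizer accuracy uses leave-one-out cross-validation
against the 12.5% chance level. Evidence on main-task partial trials is
control-subtracted per trial, then averaged over successor (lag > 0) and
predecessor (lag < 0) cells. The time-resolved variant applies the
localizer-trained model to single volumes at offsets 0, 1.5, ..., 13.5 s
(no retraining), and the group difference course is fitted with
`amplitude * hrf(t - latency)` over latencies in [-2, 8] s (bounded to one
trial's window) to estimate the time to peak; a non-positive fitted
amplitude is reported as "no transient".

**Tuning.** Localizer evidence for the tuning analysis is cross-validated
leave-one-cycle-out (8 folds, each fold one full stimulation cycle, so
training folds stay class-balanced); full leave-one-out would cost ~64x
more decoder fits at cohort scale for no change in the aggregate. Evidence
is control-subtracted before aggregation into the 4x4 coactivation matrix —
raw softmax probabilities have a positive floor at every non-stimulated
location, so without a baseline the no-coactivation model could never win.
Four models are fitted to all 16 cells: temporal (`b0 + b1 |lag|` —
symmetric in past and future), spatial (`b0 + b1 d` with chord distance d),
SR (`scale * gamma^lag`, forward-only, the 2-parameter form; the original
parameterization is not printed), and H0 (free diagonal amplitude only,
k = 1). The diagonal is included in all fits (whether the original excluded
it is not stated). V1 tuning can be run on V1 voxels with the same
machinery.

**Group statistics.** Two-sided one-sample and paired t tests, Wilcoxon
signed-rank (exact for n ≤ 25 without ties, the offered reading of the
ambiguous "non-parametric t test" — both outputs are reported side by side
where relevant), and Spearman correlation with midrank ties. No
multiple-comparison correction, matching the original captions.

## Numerical choices and degenerate inputs

* gamma and the SR tuning decay live on [0, 1]; grids at step 0.01 with
  local refinement (step 1e-3 for the lag-decay fit); scales constrained
  non-negative via closed-form projection.
* A perfect fit (RSS = 0) reports BIC = -Inf with a warning rather than an
  error, so noiseless fixtures rank as expected.
* Constant voxels z-score to 0 with a warning (filter jitter up to ~1e-16
  is treated as constant).
* Paired comparisons between models with identical error vectors return a
  zero statistic and p = 1 instead of a zero-variance error.
* All randomness flows through explicit seeds; per-subject seeds are
  derived from the cohort seed below 2^31.

## Problem sizes used in the checks

The recovery checks run at the study's conditions: n = 35 subjects, 3 runs,
default SNR. Gamma recovery probes gamma in {0.1, 0.3, 0.5, 0.7} (one
cohort each); model selection and tuning identification use 20 replicate
cohorts per generating condition; the worked analyses in `analysis/` use
n = 35 for the V1 pathway and n = 20 (decoding) or n = 12 (tuning) for the
hippocampal demonstrations. These sizes keep a full run of the suite and
scripts to a few minutes each while leaving the group-level statistics
stable.

## Known limitations

* The noise model is white and Gaussian; temporal autocorrelation would
  widen all error bars and is not represented.
* The hippocampal softmax nonlinearity means linear generative coactivation
  does not produce exactly linear evidence profiles; identification works
  at the default operating point but degrades at high decoder SNR.
* The simulator cannot robustly show the hippocampal successor-evidence
  skew and temporal tuning in one configuration, although the real data
  show both. Two mechanisms are responsible: the symmetric coactivation
  mixed into the localizer patterns cancels the forward skew at the
  decoder, and the per-subject contrast variance is dominated by random
  pattern-geometry overlaps (scaling as 1 / sqrt(voxels)), which at the
  default 64-voxel ROI drown the small anticipatory component. The
  successor-skew demonstrations therefore run under "forward-skew
  isolation" conditions — no localizer coactivation and a 512-voxel ROI —
  while tuning analyses run at the default operating point.
* Real-data mode expects preprocessed series (delimited tables or NIfTI)
  plus event tables; no FSL/FreeSurfer preprocessing, pRF estimation, or
  anatomical parcellation is included.
* The pipeline is ROI-agnostic but provides no searchlight or subfield
  analyses.
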