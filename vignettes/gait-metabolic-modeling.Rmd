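---
title: "Modeling the metabolic cost of walking with a powered ankle-foot prosthesis"
author: "gaitmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the metabolic cost of walking with a powered ankle-foot prosthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

People with a unilateral transtibial amputation walk at an elevated metabolic
cost, and powered ankle-foot prostheses — devices that add push-off work
during stance — have produced inconsistent metabolic benefits across studies.
`gaitmet` implements an analysis pipeline that asks *which* biomechanical
features of gait drive the net metabolic rate of walking with such a device:
multimodal raw signals are reduced to a trial-by-feature table, a Bayesian
additive regression tree (BART) ensemble models net metabolic rate from those
features, variable inclusion proportions (VIP) select a parsimonious feature
set, and bootstrapped accumulated local effects (ALE) rank each feature by
the size and direction of its partial effect in W/kg.

Because the human-subject dataset the design emulates is available only on
request, the package ships a synthetic-data layer with known ground truth.
Every downstream stage is therefore testable end to end: the generator's
stored truth is the oracle for signal extraction, and planted partial
effects are the oracle for model fitting, selection and ALE ranking.

## The study design the generator emulates

* 13 subjects (3 F / 10 M; age 41.5 ± 8.5 y; mass 77.4 ± 15.2 kg including
  the prosthesis; height 1.75 ± 0.08 m; prosthesis shoe sizes 22–30 cm),
  each walking at 1.25 m/s on an instrumented treadmill.
* 16 prosthesis configurations: 4 foot stiffness categories (−2, −1, Rec,
  +1) × 4 battery power settings (NoPower, Rec, +10%, +20%). The (−1,
  NoPower) passive-elastic condition is the per-subject baseline.
* 195 trials (13 × 16 = 208 minus 13 unreported losses; the generator takes
  the dropped-trial count as a parameter and never drops baselines), and 182
  modeling trials after baseline rows leave with the z-scoring.
* Per trial: 30 s of per-leg 3-axis ground reaction forces (1000 Hz),
  heel-marker trajectories (100 Hz), joint-angle series (100 Hz, emitted
  directly by the generator — inverse kinematics is upstream of this
  pipeline's scope), surface EMG (1000 Hz; 4 affected-side and 7
  unaffected-side muscles), and breath-averaged gas exchange over the 5-min
  metabolic trial (gases span 300 s even though motion capture spans 30 s).

### Raw-signal model

The vertical GRF stance template is two Gaussian bumps (peaks ≈ 1.05–1.15
body weight at 27% and 73% of stance, SD 0.15 stance) on a smooth edge
window, plus a mid-stance filler solved at generation time so each leg's
stride-averaged vertical force equals half body weight — steady-gait impulse
balance, which keeps the integrated COM velocity physiological. Stance
occupies 62% of the stride and contralateral stances overlap by ≈ 12%
(double support). The fore-aft GRF is braking-then-propulsive
(±0.17 BW); the mediolateral GRF is a small midline-directed curve with an
early lateral dip.

Two printed device calibrations enter the waveforms:

* **Power.** The trailing affected-leg positive transition-work target rises
  0.025 J/kg per 10% power step. The generator hits the target by a secant
  search on the affected leg's propulsive amplitude, evaluating the work
  integral on its own clean signals; stored truth is therefore accurate to
  the quadrature, not to a linearization.
* **Stiffness.** The prosthetic ankle angle follows a compliance model: peak
  heel/forefoot moments divided by rotational stiffnesses of 0.065 + 0.01 ×
  category and 0.45 + 0.12 × category kN·m/rad.

Ground truth is computed from the *clean* waveforms: event times are the
analytic 50 N crossings (solved with `uniroot`), and COM velocity /
transition work come from the same trapezoidal integration definitions the
extractor uses, but on noise-free, unfiltered signals. The emitted signals
carry 1 N GRF noise and 0.2 mm marker noise, so the self-consistency checks
(events within 1 sample, work within 2%) exercise a genuinely different data
path.

What the generator does **not** emulate: marker-cluster kinematics and joint
moments, swing-phase kinematic detail beyond what peak extraction needs,
actuator dynamics, and inverted-pendulum work symmetry — the waveforms
represent asymmetric prosthetic gait, so leading-leg negative and
trailing-leg positive work are deliberately unequal. Passing tests therefore
show that the *pipeline* is correct, not that the waveforms are
physiologically exact.

### Feature-level generator

For model/selection/ALE testing the feature-level generator skips signals
entirely: biomechanical features are standard normals with block correlation
ρ = 0.5 inside each registry category (a shared-factor construction), which
deliberately stresses ALE's robustness to correlated predictors, and

```
net metabolic rate = 3.1 + Σ partial effects + N(0, 0.1) W/kg.
```

The default spec plants five effects with amplitudes 0.6, 0.5, 0.4, 0.3 and
0.2 W/kg — spanning the 0.18–0.65 W/kg range the analysis is designed to
resolve — using saturating, linear, hinge and quadratic shapes with mixed
signs. Each effect is calibrated so its amplitude equals the P90 − P10
spread of the effect values under the feature's generating distribution,
making amplitudes directly comparable to ALE effect sizes. Mean net
metabolic rate is 3.1 W/kg so those amplitudes correspond to ≈ 6–20% of the
mean, as in the emulated study. Missingness, when injected, is MCAR — only a
rate is known, not a mechanism.

## Processing conventions

* **Filtering.** All zero-phase (forward–backward) Butterworth chains halve
  the per-pass order and widen the per-pass cut-off by the dual-pass factor
  `(√2 − 1)^(−1/(2n))`, so the net response has the stated order's rolloff
  *and* passes −3 dB at the stated cut-off (the textbook gait-analysis
  convention). GRF and joint-angle series are filtered at 7 Hz (4th order)
  before peak/work computation; EMG is demeaned, high-passed at 20 Hz (2nd
  order), rectified, low-passed at 6 Hz (2nd order) and clamped at zero.
  Heel markers are used unfiltered for step lengths/widths: the heel
  trajectory has a slope corner at contact that filtering would smear into a
  systematic millimetre-scale step-length bias.
* **Events.** 50 N threshold crossings with sub-sample linear interpolation,
  0.2 s stance debounce, 50 ms gap bridging; stances touching the record
  edges are dropped as incomplete.
* **Transition work.** COM velocity is integrated per stride with the
  constant chosen so the stride-average velocity is (1.25, 0, 0) m/s in the
  belt frame; per-leg external power is integrated trapezoidally over each
  double-support window with interpolated fractional endpoints, positive and
  negative portions separately.
* **Outliers.** Single-pass per-group (subject × variable) 3 SD removal in
  leave-one-out form — each stride value is judged against the mean/SD of
  the *other* values, so a gross outlier cannot mask itself by inflating the
  group SD (a plain-SD pass would keep a value like 100 among {1,1,1,1,100}).
  Variables losing over 30% of values are excluded from the registry for
  that run.
* **Normalization.** Stride/step lengths and step width divide by height;
  transition work and GRFs divide by mass (prosthesis included); then each
  z-scored feature and the outcome are centered and scaled per subject by
  the baseline trial's stride-level mean and SD. A zero baseline SD falls
  back to the pooled across-subject SD (flagged), and constant features
  z-score to zero rather than dividing by zero.
* **Imputation.** missForest-style: missing cells start at column means,
  each incomplete column is iteratively re-fit with a `ranger` regression
  forest on the others, stopping when the normalized change in imputed
  values stops decreasing. Forests run single-threaded with fixed seeds, so
  completions are reproducible.

## The model and its settings

The BART engine is a Metropolis-within-Gibbs backfitting sampler written for
this package (no BART implementation exists in the dependency set): each
sweep proposes grow / prune / change moves per tree against the residual of
the other trees, with conjugate leaf-value and error-variance draws, the
depth prior `α (1+d)^(−β)` (α = 0.95, β = 2), leaf prior SD
`0.5/(k√m)` on the internal [−0.5, 0.5] outcome scale, and the (ν, q)
scaled-inverse-χ² error prior. Split candidates are up to 100 midpoints of
the observed values per feature; leaves keep at least 5 training rows. All
randomness flows through R's RNG, so a seed fixes the trace exactly.

The cross-validation grid mirrors the canonical tool's documented defaults —
trees ∈ {50, 200}, k ∈ {2, 3, 5}, (ν, q) ∈ {(3, 0.9), (3, 0.99),
(10, 0.75)} — with subject-stratified folds (trials cluster within subject;
fold construction is otherwise unstated upstream, so stratification is this
package's choice). Ties break toward fewer trees, then grid order. Burn-in
and draw counts are unstated upstream; the defaults are 250/1000 for final
models, and the VIP-test and feature-test fits use 100/200 with 50 trees — a
deliberate economy, since those fits only need a stable importance ranking
and a plateau location, and the parameter-recovery suite confirms they
deliver one. The 20 VIP-test models vary only in seed.

Selection follows the two-stage recipe: anatomical-pair correlation pruning
at |r| > 0.8 (replication mode removes the fixed six partners — ankle
eversion, hip external rotation, hip adduction, both sides; discovery mode
removes the lower-VIP member of any over-threshold pair), VIP averaging over
20 fits, one fit per top-k feature set, and the smallest k within 1%
(relative, `≥ 0.99 × max`; the absolute reading is available via
`select_k(relative = FALSE)` and is nearly identical when the maximum is
close to 1).

## ALE and effect sizes

`ale_curve` is the standard first-order construction: quantile breakpoints
(capped at one fewer than the distinct values), mean prediction differences
across each interval, cumulative sum, and centering so the sample-weighted
curve mean is zero. `bootstrap_ale` repeats it on 50 subsamples of 40 trials
drawn *without* replacement (a finite trial set is being subsampled; the
with-replacement variant is a one-line change), pools every replicate's
breakpoint values, and bins them into 10 even bins over the pooled range;
empty bins are reported with count 0, never interpolated, because the
display convention sizes points by bin count. The effect size is the
P90 − P10 spread of the pooled curve values — the trendline values entering
the plot, not the binned means (both are computable; the pooled-values
reading is the default). Features whose effect exceeds the model's in-sample
RMSE (W/kg) are retained, and the direction that reduces the outcome comes
from the first-vs-last populated bin means.

The outcome enters the model in raw W/kg in the shipped analyses, so effect
sizes are directly in W/kg; the z-scored outcome scale is carried alongside
(`zscore_to_baseline` transforms it identically) and converts via the stored
baseline SDs.

Shape recovery is assessed as the correlation between binned ALE means and
the true partial effect, *weighted by bin count*: sparse extreme bins sit
where a tree ensemble rightly flattens beyond the data support (most visible
for the quadratic effect's steep tails), and the count weighting matches how
the binned plot is actually read.

## Numerical choices and degenerate inputs

* Work integrals: trapezoidal quadrature at 1000 Hz (second-order accurate);
  event times interpolated between samples.
* `signal::filtfilt` applies no end-condition handling, so every chain
  odd-reflects the signal by `6 fs / fc` samples at each end and trims,
  letting start-up transients decay inside the pads.
* Zero-variance features: no split candidates (BART ignores them), zero ALE
  curves with a warning, z-scores of exactly zero.
* Vertical-GRF windows without a two-peak structure are flagged
  `single_peak` and the second peak left missing (imputable), mirroring how
  a flat-footed stance would be handled.
* Empty double-support windows raise errors; windows extending beyond the
  integrated stride span are skipped.

## Problem sizes in the shipped runs

The test-suite and acceptance runs use the study-scale feature cohort (182
rows × 50 features) throughout; signal-level checks run on single 20–30 s
trials, and the pipeline round-trip tests use 2–5 subjects. The 20-seed
recovery suite re-runs VIP averaging (20 fits) and the full 50-point
incremental curve per seed with the economical selection settings above.

## Known limitations

* The raw-signal generator is a waveform emulator, not a musculoskeletal
  model; its joint-angle channels are stylized sinusoid/Gaussian composites.
* Signal-level outcomes are generated from configuration and subject
  effects, not from the biomechanical features themselves, so end-to-end
  effect recovery is exercised on the feature-level cohort only.
* The sampler omits sparsity priors and heteroskedastic extensions by
  design, matching the described usage.
* Second-order (interaction) ALE surfaces are out of scope.
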