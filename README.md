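# gaitmet

Biomechanical drivers of the net metabolic rate of walking with a powered
ankle-foot prosthesis.

For people with unilateral transtibial amputation, stance-phase powered
prostheses can add push-off work, yet measured metabolic benefits have been
inconsistent across studies. This package implements the analysis that asks
*which* gait features drive the net metabolic rate in such an experiment: it
reduces multimodal raw signals (per-leg ground reaction forces, heel
markers, joint angles, surface EMG, breath-by-breath gas exchange) to a
trial-by-feature table, models net metabolic rate with a Bayesian additive
regression tree (BART) ensemble, selects features by variable inclusion
proportion (VIP), and ranks each feature's partial effect with bootstrapped
accumulated local effects (ALE). A synthetic-data layer with known ground
truth makes every stage testable without any subject data.

It is written for movement-physiology and rehabilitation researchers who
want a reproducible, fully testable reimplementation of this modeling
pipeline, or a harness to study its statistical behavior.

## The model

The outcome is the net metabolic rate of treadmill walking at 1.25 m/s,

```
P_net = P_gross − P_rest        [W/kg],  P = 16.58 · V̇O₂ + 4.51 · V̇CO₂ (rates in mL/s)
```

modeled from 50 features — subject covariates, prosthesis stiffness/power
settings, spatiotemporal parameters, stance-phase joint-angle and GRF peaks,
integrated EMG, and individual-limb step-to-step transition work

```
W±_leg = ∫_DS [ F_leg · v_com ]± dt ,    v_com = c + ∫ (F_tot − m g ẑ)/m dt
```

integrated over double-support windows bounded by 50 N vertical-GRF
crossings. The regression is a sum of m regularized trees,

```
y = Σ_{j=1..m} g(x; T_j, M_j) + ε,   ε ~ N(0, σ²)
```

sampled by Metropolis-within-Gibbs backfitting (grow/prune/change proposals,
conjugate leaf and σ² draws; the sampler lives in `src/bart.cpp`). Feature
importance is the VIP — the fraction of split rules using a feature,
averaged over 20 replicate fits — and the final feature count is the
smallest k whose top-k model reaches within 1% of the best pseudo-R².
Each feature's effect is summarized by bootstrapped ALE (50 resamples of 40
trials, 10 even bins) and the scalar effect size P90 − P10 of the pooled
curve values, in W/kg; features with effects above the model's in-sample
RMSE are retained and ranked.

## Worked example

```r
library(gaitmet)
# simulate the study-scale cohort: 13 subjects x 16 configurations,
# 13 trials lost, baseline rows excluded -> 182 modeling trials,
# 5 planted partial effects with amplitudes 0.6/0.5/0.4/0.3/0.2 W/kg
sc <- standard_cohort(seed = 1)
dim(sc$X)
#> [1] 182  50

fit <- bart_fit(sc$X, sc$y, bart_hyperparams(n_trees = 200, seed = 7))
fit
#> BART ensemble: 200 trees, 1000 kept draws, 50 features
#>   in-sample pseudo-R2 0.988, normalized RMSE 1.93%

# VIP ranking puts the five planted effects in the top five ranks
vip <- average_vip(sc$X, sc$y, n_models = 20,
                   hp = bart_hyperparams(n_trees = 50, n_burn = 100,
                                         n_draws = 200), seed = 100)
match(sc$active, names(vip))
#> [1] 3 1 4 2 5

curve <- incremental_curve(names(vip), sc$X, sc$y,
                           hp = bart_hyperparams(n_trees = 50, n_burn = 100,
                                                 n_draws = 200), seed = 200)
(k <- select_k(curve, tolerance = 0.01))   # smallest k within 1% of best R2
#> [1] 9
all(sc$active %in% names(vip)[1:k])
#> [1] TRUE

# bootstrapped ALE effect of the strongest planted feature
b <- bootstrap_ale(fit, sc$X, "work_trailing_affected_positive",
                   sample_size = 40, n_reps = 50, n_bins = 10,
                   seed = 42, thin = 10)
round(b$effect_size, 2)   # W/kg; generating amplitude was 0.6
#> [1] 0.49
round(model_rmse(fit), 3) # retention threshold (in-sample RMSE, W/kg)
#> [1] 0.041
```

The numbers mean: the ensemble explains 98.8% of outcome variance in-sample
with a 1.93% range-normalized RMSE; the five planted effects occupy VIP
ranks 1–5 and all survive selection at k = 9; the strongest planted effect
(amplitude 0.6 W/kg) is recovered with an ALE effect size of 0.49 W/kg,
an order of magnitude above the 0.041 W/kg retention threshold.

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline over synthetic data and
write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | feature-level cohort (`cohort.csv`, `ground_truth.yaml`) and raw-signal trial bundles (`grf.tsv`, `markers.tsv`, `angles.tsv`, `emg.tsv`, `gases.tsv`, `meta.yaml`) |
| `02_extract_mechanics.R` | gait events, strides, transition work (`strides.csv`, `transition_work.csv`); demonstrates the 0.025 J/kg-per-power-step push-off increment |
| `03_fit_model.R` | subject-stratified CV, final BART fit (`model_summary.json`, `vip.csv`) |
| `04_select_features.R` | VIP averaging, incremental curve, within-1% selection (`ranking.csv`, `selection_curve.csv`) |
| `05_ale_effects.R` | bootstrapped ALE for every feature (`ale_curves.csv`, `effect_sizes.csv`) |

`run_all(run_config(...))` performs the same stages as one call, in
`discovery` mode (feature-level cohort, data-driven selection) or
`paper_replication` mode (raw-signal cohort, fixed anatomical pruning and
the fixed 50-feature registry), writing a manifest with per-file checksums.

The methods vignette (`vignettes/gait-metabolic-modeling.Rmd`) documents the
waveform and effect models, the processing conventions, and every numerical
choice.

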