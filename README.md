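# raceRP

Race-to-threshold accumulator modelling and readiness-potential (RP)
analysis for deliberate versus arbitrary decisions.

## The problem

The readiness potential — a slow negative EEG deflection at central
electrodes (Cz) that precedes self-initiated movement — is classically read
as a marker of unconscious movement preparation. An alternative account
holds that it is an artifact of how movement-locked averages sample
autocorrelated noise: a leaky stochastic accumulator driven by noise
produces an RP-like ramp whenever its threshold crossings are used as the
time-locking events. Under that account the RP should appear for
*arbitrary* decisions (driven by noise) but vanish for *deliberate* ones
(driven by the values of the alternatives), because in deliberate decisions
the recorded noise accumulator is interrupted at a random level by a
separate value-comparison process.

`raceRP` implements that dual-component model and everything needed to test
it end to end:

- **Model** (`simulate_accumulator`, `run_race`, `run_trial`,
  `simulate_condition`): each decision is a race between two leaky
  stochastic accumulators (congruent and incongruent with the subject's own
  preference ratings),

  x_{i+1} = x_i + (I − k·x_i)·Δt + c·ξ_i·√Δt,

  with drift *I*, leak *k*, noise scale *c*, Gaussian deviates ξ, Δt =
  0.001 s, and a fixed decision threshold θ = 0.3. Arbitrary conditions are
  decided by the noise (SMA) pair; deliberate conditions by the value
  (Region X) pair while an unbounded SMA pair (drifts divided by 1.45)
  integrates in parallel as the simulated recording site.
- **Fitting** (`fit_gamma_cdf`, `rt_distribution_error`,
  `grid_search_fit`): condition parameters are fit to a reaction-time
  distribution (gamma-CDF intersection-over-union error) and a
  choice-consistency score, with equal weights, by an iterative 5×5×5×5
  zooming grid search.
- **RP prediction** (`epoch_model_trial`, `average_model_rp`,
  `predict_rp`): null-padded epoching of winner and loser noise traces over
  the last 2 s before each crossing, averaged and sign-flipped into the
  model's movement-locked ERP.
- **EEG pipeline** (`apply_filters`, `reject_artifacts`, `exclude_trials`,
  `epoch_recording`, `compute_rp`, `compute_lrp`): zero-phase FIR filtering
  (0.1 Hz high-pass, 59–61 Hz notch), amplitude/difference/flatline
  artifact rules with ±150 ms expansion, behavioral trial exclusion
  (<200 ms, >10 s, ±3 SD, wrong key), response- or stimulus-locked epochs
  with either baseline, RP mean amplitude over the last 500 ms at Cz, and
  the C3−C4 lateralized readiness potential by response hand.
- **Statistics** (`trend_slope_average`, `trend_slope_trials`,
  `cluster_permutation_vs_zero`, `saccade_count`, `consistency_grade`):
  decimated trend regression (25 Hz anti-aliasing, every 10th sample),
  robust single-trial slopes (IRLS, bisquare), one-sample cluster-based
  permutation testing (|t| > 2 cluster threshold, sign-flip null, α =
  0.05), radial-EOG saccade counting, and the behavioral consistency grade.
- **Synthetic data** (`generator_config`, `generate_behavior`,
  `generate_eeg`): gamma reaction times with condition means
  2.13/2.52/0.98/1.00 s, congruent-choice probabilities
  0.99/0.83/0.54/0.49, 512 Hz EEG with 1/f noise, a −2.5 µV pre-movement
  ramp at Cz in arbitrary trials only, a lateralized C3/C4 component, EOG
  saccade bursts, blinks, and occasional large artifacts.
- **Workflow** (`analyze_dataset`, `run_workflow`): one seeded path from
  synthetic data through the full analysis, writing CSV/JSON results.

## Worked example

```r
library(raceRP)

tab <- default_parameter_table()       # best-fit parameters per condition
cond <- condition_from_table(tab, "deliberate", "easy")
sim <- simulate_condition(cond, 1000, seed = 1)
cat(sprintf("consistency: %.3f\nmean RT: %.2f s\n",
            sim$consistency, mean(sim$rt, na.rm = TRUE)))
#> consistency: 0.995
#> mean RT: 2.02 s

rp_arb <- predict_rp(condition_from_table(tab, "arbitrary", "easy"),
                     1000, seed = 2)
rp_del <- predict_rp(condition_from_table(tab, "deliberate", "easy"),
                     1000, seed = 3)
cat(sprintf("final-0.5 s slope, arbitrary-easy: %.3f\n",
            model_rp_slope(rp_arb)))
cat(sprintf("final-0.5 s slope, deliberate-easy: %.3f\n",
            model_rp_slope(rp_del)))
#> final-0.5 s slope, arbitrary-easy: -0.228
#> final-0.5 s slope, deliberate-easy: -0.041
```

The simulated deliberate-easy condition chooses the higher-rated
alternative on ~99% of trials with a ~2 s mean reaction time, and the
model's movement-locked noise-component average ramps steeply downward
before arbitrary decisions (an RP) but stays nearly flat — about 18% of the
arbitrary slope — before deliberate ones.

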