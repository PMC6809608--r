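---
title: "A dual-component race model of deliberate and arbitrary decisions, and the readiness potential it predicts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-component race model of deliberate and arbitrary decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raceRP)
```

## The model

Every simulated decision is a race between two leaky stochastic
accumulators, one per decision alternative. Each accumulator follows the
Euler–Maruyama discretization

$$x_{i+1} = x_i + (I - k\,x_i)\,\Delta t + c\,\xi_i\sqrt{\Delta t},
\qquad x_0 = 0,$$

with drift rate $I$ (units: activation/s), leak $k$ (1/s), noise scale $c$
(activation/$\sqrt{s}$), standard-normal deviates $\xi_i$, and
$\Delta t = 0.001$ s. The first accumulator to reach the threshold
$\theta = 0.3$ wins: it fixes the choice (congruent or incongruent with the
subject's earlier preference ratings) and the reaction time (crossing
sample × $\Delta t$). The leak bounds the deterministic part of the
trajectory at $I/k$, which is why a noiseless accumulator crosses at
$t^* = -\log(1-\theta k/I)/k$ only when $\theta k/I < 1$ — this closed form
is the package's integration oracle.

The model has two such race pairs:

- a **noise (SMA) component**, the simulated generator of activity under
  the Cz electrode, and
- a **value (Region X) component** representing value comparison.

In *arbitrary* conditions the SMA race decides. In *deliberate* conditions
the Region X race decides while the SMA pair integrates without any
threshold (the threshold is set to infinity) and with drift rates divided
by 1.45 — the ratio of central to whole-scalp EEG activity used to scale
the recording site relative to the deciding region; its traces are cut at
the Region X crossing. Both accumulators of a pair share $k$ and $c$; only
the drifts differ. Four mutually independent noise streams feed a trial's
four accumulators, and a tie at the same crossing sample (probability of
order $\Delta t$) is resolved by a fair coin from the same stream.

`default_parameter_table()` carries the best-fit parameters per condition:

```{r}
default_parameter_table()
```

Simulating 1000 trials per condition reproduces the behavioral summaries
these parameters were fit to: consistencies near 0.99/0.83/0.54/0.49 and
mean reaction times near 2.13/2.52/0.98/1.00 s. One caveat worth naming:
for arbitrary-hard the congruent drift (0.22) strictly exceeds the
incongruent one (0.20), so the model's asymptotic congruent-choice fraction
is ≈ 0.53 and can never fall to the empirical 0.49; at 1000 runs the
simulated value fluctuates around 0.53 ± 0.016.

### Undecided trials

Simulation is capped at `t_max = 20` s, mirroring the task's response
deadline. Trials with no crossing are flagged, excluded from reaction times
and consistency, and counted; all-undecided parameter sets raise an error.

## Fitting

A condition is scored against two targets with equal weights:

- **RT error** — both the target and the model reaction times are reduced
  to gamma CDFs on a fixed 0–20 s grid with 1 ms spacing, and the error is
  one minus the ratio of the areas under the pointwise minimum and maximum
  of the two curves. CDFs (not densities) enter the ratio, the grid is the
  simulation grid, and the measure is symmetric and lies in [0, 1].
- **Consistency error** — the absolute difference between model and target
  congruent-choice fractions.

`fit_gamma_cdf()` fits the 2-parameter gamma (no location shift) by
least-squares against the empirical CDF on that grid; the optimizer
evaluates the objective on every 10th grid point, which rescales the
Riemann sum without moving its minimizer, and is started from moment
estimates. Degenerate (constant) or tiny (< 10) samples are rejected.
Across-subject averaging of fitted CDFs, when used, is pointwise on the
grid.

`grid_search_fit()` implements the zooming grid search: each of the four
free parameters (congruent drift in [0.05, 0.4]; incongruent drift as a
fraction of the congruent one in [0.2, 1]; leak in [0.2, 0.55]; noise in
[0.01, 0.3]; threshold fixed) is divided into five equal parts, all
$5^4 = 625$ combinations are simulated (1000 runs each by default), and the
search zooms to the interval between the two grid neighbors of the best
entry, stopping when every parameter interval is narrower than 0.025 or the
best error drops below 0.025. Two choices the search space left open:

- the incongruent-drift range stays *relative* to the current congruent
  drift at every zoom level (the alternative — freezing it to an absolute
  interval after level 1 — behaves almost identically away from the box
  edges);
- every grid entry is evaluated with **common random numbers** (the same
  seed), so between-entry comparisons are free of simulation noise; the
  price is that the whole search is conditionally biased by one noise
  realization, which the parameter-recovery tests bound.

A minimum on the boundary of the initial box triggers a warning rather than
an error; the initial ranges were chosen wide enough that interior optima
are the norm. Weakly identified directions exist: for near-symmetric
(arbitrary-like) targets, consistency pins only the drift *ratio* and the
RT distribution constrains $(I, k, c)$ jointly, so distinct $(k, c)$ pairs
can fit almost equally well — the deliberate-hard condition is known to
have two nearly equivalent basins. Parameter-recovery checks therefore use
a well-identified (deliberate-easy-like) target.

## The predicted readiness potential

For each decided trial the two SMA traces are averaged pointwise (an
electrode sees both), the last 2000 samples before the crossing are taken,
and earlier-crossing trials are padded at the head with missing markers
that never enter averages. The per-sample mean over trials is flipped
vertically (accumulation toward threshold maps to scalp negativity), for
deliberate and arbitrary conditions alike. Averaged over 1000 runs this
yields a steep negative-going ramp before arbitrary decisions and a weak,
almost perfectly linear trend before deliberate ones (the quadratic
component measures below a quarter of the linear trend's scale). Outputs
stay in model activation units; no rescaling to microvolts is attempted, so
comparisons to EEG are qualitative (shape and ratio, not amplitude). During
arbitrary trials the value pair is outcome-irrelevant and is not simulated
unless `simulate_region_x = TRUE`.

## The EEG pipeline and its contracts

- **Filtering**: zero-phase (forward–backward) FIR filters designed with
  Hamming windows; 0.1 Hz high-pass with 0.1 Hz transition width, 59–61 Hz
  notch with 1 Hz transitions, optional low-pass. Kernels are combined by
  convolution and applied through FFT convolution with odd-reflection
  padding, so minutes-long recordings filter in seconds and edges do not
  ring. A 0.01 Hz high-pass variant is available through the
  `highpass_hz` argument.
- **Artifacts**: per channel, amplitude beyond ±100 µV, a swing above
  100 µV within any 200 ms window, or peak-to-peak activity below 0.5 µV
  sustained over 100 ms (a flatline; peak-to-peak range was chosen over
  absolute amplitude, which a high-passed signal hovers around anyway).
  Violations mark the interval ±150 ms for all channels.
- **Trial exclusion**: wrong key, RT < 200 ms, RT > 10 s, then a single
  (non-iterated) ±3 SD rule per subject × condition computed on the
  survivors of the absolute rules.
- **Epoching**: windows are half-open in samples — $[-2, 0.2)$ s at 512 Hz
  is exactly 1126 samples — locked to response or stimulus, with the
  baseline mean (default $[-1, -0.5)$ s before *stimulus* onset; a
  movement-locked variant is one argument away) subtracted per channel.
  Out-of-bounds epochs and artifact overlaps drop the trial with a recorded
  reason, so trial counts always reconcile.
- **RP**: mean over kept trials, then over the last 500 ms, at Cz, per
  subject × condition; subjects under 30 kept trials are flagged. **LRP**:
  mean left-hand (C3−C4) minus mean right-hand (C3−C4) per subject. The
  average-reference operator exists but the synthetic workflow leaves it
  off — with a handful of synthetic channels the "average" would mostly be
  the signal itself, not a neutral reference.
- **Trend regression**: a 25 Hz low-pass, then every 10th sample (both for
  run time and because decimation brings autocorrelated EEG closer to the
  regression's independence assumption), then OLS for per-subject averages
  and bisquare IRLS (max 50 iterations, OLS fallback with a warning on
  non-convergence) for single trials; a subject counts as reliably ramping
  down when the t test of its trial slopes survives Bonferroni correction
  and the mean slope is negative.
- **Cluster test**: per-sample one-sample t across subjects; runs with
  |t| > 2 form clusters; masses are sums of t; the null is built from
  random per-subject sign flips (default 1000 permutations), pooling
  positive and negative clusters against the max-|mass| distribution
  (two-tailed; a one-tailed variant would split the threshold). p-values
  use the add-one rule, so they can never drop below 1/(permutations + 1).
- **Saccades**: the radial signal (mean of the four EOG channels) is
  band-passed 30–100 Hz with a deliberately wide 15 Hz transition — a short
  kernel keeps a 10 ms burst from ringing into spurious distant
  detections. Excursions beyond 2.5 *standardized IQRs* (IQR × 0.7413, the
  normal-consistent robust SD — the factor that makes 2.5 units behave like
  2.5 robust standard deviations) lasting over 2 ms are saccades;
  excursions separated by less than 50 ms merge into one. At 512 Hz the
  band-pass smears bursts by roughly ±25 ms, so events about 60 ms apart
  can genuinely blur; the refractory rule is exercised at 30 ms (merged)
  and 120 ms (distinct).

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without any
recorded data. Its defaults are the study conditions the analysis assumes:
18 subjects, 90 trials per condition, gamma reaction times with means
2.13/2.52/0.98/1.00 s (shape 6, i.e. a coefficient of variation of ~0.41,
typical of trial-level response times), congruent-choice probabilities
0.99/0.83/0.54/0.49, 512 Hz recordings, inter-trial fixations uniform on
1–1.5 s and a 1 s post-response highlight. The EEG layer adds, per channel,
1/f noise (spectrally shaped white noise, exponent 1, 10 µV RMS — an
autocorrelated stand-in for background EEG), and injects:

- a linear ramp from 0 at −1.2 s to −2.5 µV at the response at Cz (half
  that on neighbors), in **arbitrary trials only** — the simplest shape
  consistent with the intended onset and magnitude (a quadratic variant
  sits behind `rp_shape`);
- a lateralized ramp (−1.5 µV over the final 0.3 s) at the electrode
  contralateral to the response hand — C4 for left-hand responses — so the
  left-minus-right difference doubles it with a *positive* sign;
- Poisson EOG saccade bursts at 3.3/s (≈ 1.65 per 500 ms window once
  detected), slow blink transients, and occasional ±150 µV artifacts.

What the generator does **not** emulate: volume conduction and realistic
scalp topography (the spatial falloff is a free parameter, not a claim),
blink/saccade leakage into scalp channels, non-stationary noise, and any
dependence of the EEG on trial difficulty. Passing tests therefore show
that the pipeline recovers what the generator injects under realistic
noise — not that real cortex produces these signals.

On generator defaults the full pipeline reproduces the dissociation it was
built around: the last-500 ms Cz amplitude differs from zero and a
prolonged pre-response cluster appears for arbitrary conditions only, and
single-trial robust slopes are reliably negative for arbitrary trials only.
With the ramp injection disabled everywhere, the cluster test's
false-positive rate sits at its nominal α (0.046 measured over 500 null
datasets).

## Numerical choices and problem sizes

Degenerate inputs fail fast with named errors: non-finite parameters,
thresholds ≤ 0, corner frequencies at or beyond Nyquist, constant RT
samples, missing EOG channels, a response hand with no trials, fewer than
6 subjects or 100 permutations in the cluster test. The simulation core is
compiled (Rcpp) and consumes R's RNG stream, so `set.seed()` governs
everything; noiseless accumulators draw no random numbers.

Test and example sizes were chosen to keep the whole suite comfortably
reproducible on a laptop: 1000 runs per condition for behavioral
reproduction (binomial SE ≈ 0.016), 1000 model runs for RP prediction, a
2-zoom-level parameter recovery at 1000 runs per grid entry, 500 replicates
for permutation-test calibration, and the full 18 × 90-trial default for
the end-to-end dissociation. The grid search at its full, unreduced
schedule is the only expensive object (minutes per zoom level); `n_runs`,
`n_grid` and `max_levels` scale it.

## Known limitations

- Model ERPs are in activation units; only shapes and ratios are
  comparable to microvolt data.
- The fitting surface is flat in $(k, c)$ for near-symmetric conditions;
  report recovered parameters together with their search trace.
- The ±3 SD exclusion rule is applied once, not iterated.
- The saccade detector's temporal resolution is bounded by the band-pass
  kernel (~25 ms at 512 Hz).
- `run_workflow()` keeps recordings in memory per subject and writes only
  derived results; raw synthetic EEG is regenerated from seeds rather than
  stored.
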