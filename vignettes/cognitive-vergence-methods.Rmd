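---
title: "Measuring cognitive vergence from binocular gaze recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive vergence from binocular gaze recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogvergence)
```

## The phenomenon and the measurement

When a visual stimulus captures attention, the two eyes briefly rotate
toward each other: a small, transient convergence time-locked to stimulus
onset, often called *cognitive vergence*. In an oddball task — frequent
"distractor" stimuli interleaved with rare "target" stimuli that require a
response — this transient is larger for targets than for distractors, so
its modulation can serve as an objective index of stimulus processing.

`cogvergence` implements the full measurement chain from raw binocular
gaze samples to that modulation index:

1. **Geometry.** Each eye's on-screen gaze coordinate (pixels) is
   converted to an azimuth in a common head-centred frame,
   $\theta = \operatorname{atan}\!\big((x_{mm} - e)/d\big)$, where
   $x_{mm}$ is the gaze point in mm from the screen centre, $e$ the
   signed eye offset ($\pm$ IPD/2) and $d$ the viewing distance. The
   vergence angle is $\gamma = \theta_L - \theta_R$ (degrees), which for
   symmetric fixation at distance $d$ equals the closed form
   $2\operatorname{atan}\!\big(\mathrm{IPD}/2d\big)$ — the identity the
   test suite verifies to $10^{-9}$ relative error.
2. **Epoching.** Samples are cut into per-trial epochs around stimulus
   onset, invalid samples (non-zero tracker validity code in *either*
   eye — vergence needs both) are counted, trials with 15 or more
   invalid samples in the epoch are discarded, and the remaining valid
   samples are linearly interpolated onto an evenly spaced grid anchored
   at onset.
3. **Relative modulation.** Each retained trial is summarized by
   $$V(t) = \frac{\gamma(t) - \gamma_0}{\max_{t \in W}|\gamma(t) - \gamma_0|},$$
   with $\gamma_0$ the interpolated vergence at stimulus onset and the
   maximum taken over the normalization window $W$. $V$ is
   dimensionless, 0 at onset, and reaches $|V| = 1$ inside $W$; it
   removes between-trial and between-device differences in absolute
   response amplitude, which is what makes two very different trackers
   comparable.
4. **Windowed measures.** Mean $V$ in the *initial* (0–200 ms), *peak*
   (400–433 ms) and *delay* (600–1250 ms) windows, per condition; all
   windows are closed intervals on the grid.
5. **Modulation index.** With $T$ ($D$) the mean over target
   (distractor) trials of the 300–600 ms window-averaged response,
   $$mi = \frac{T - D}{T + D}.$$
   Positive $mi$ means a stronger target response. The index is scale
   invariant but unbounded as $T + D \to 0$, so per-subject magnitudes
   above 1 are legitimate; when $|T + D| < 10^{-12}$ the index is
   undefined and excluded from group means with an explicit count.

`vergence_analysis()` fits this chain to a set of recordings and returns
a classed object with `print`, `summary`, `coef` (per-subject $mi$ by
tracker) and `plot` (condition-averaged $V(t)$) methods;
`run_simulate()`, `run_analyze()` and `run_report()` provide the same
pipeline over CSV directories.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `viewing_distance` | 500 | mm | seated "about 50 cm" from the laptop screen |
| screen | 1366 × 768 px, 345.2 × 194.2 mm | — | 15.6″ 16:9 HD panel |
| `ipd` | 63 | mm | adult population mean; rarely measured per subject |
| `epoch_window` | (−200, 2000) | ms | analysis windows end at 1250 ms; −200 ms of pre-stimulus supports baseline inspection |
| `norm_window` | (0, 2000) | ms | the stimulus epoch; must contain every response window |
| `exclusion_threshold` | 15 | samples | half an epoch second at 30 Hz; the rule that defines a recoverable trial |
| windows | initial (0,200), peak (400,433), delay (600,1250), mi (300,600) | ms | the response components of the oddball vergence transient |
| `t_test` | `"welch"` | — | robust to the unequal condition variances typical of these data; pooled Student *t* available |

Two choices deserve comment because the measurement definition leaves
them open. First, $\gamma_0$ is the **single** interpolated sample at the
onset grid point, not a pre-stimulus average: V is defined per trial
relative to "the value at stimulus onset", and averaging would leak
pre-stimulus samples into the normalizer. Second, normalization is
**per trial**, with condition averaging applied afterwards: the formula
is a per-trial quantity, and averaging first would let high-amplitude
trials dominate the mean curve. The 400–433 ms peak window is exactly
one 30 Hz sampling interval wide; on an onset-anchored grid it contains
the single sample at 400 ms, and `window_mean()` accepts one-point
windows by design.

## The simulator

`simulate_cohort()` generates the design the analysis assumes: 28
subjects, 100-trial sessions (exactly 20 targets — the design fixes the
percentage, so counts are not Bernoulli draws), 2000 ms mask + 2000 ms
stimulus, sampled at 30 Hz by two devices simultaneously. The
event-locked response is a parametric kernel — zero until a 300 ms
latency, raised-cosine rise to the peak at 450 ms, exponential
relaxation (τ = 150 ms) to a sustained plateau through 1250 ms, then
relaxation to baseline. Target kernels default to 0.3° peak with a 40%
plateau; distractor kernels to 0.05° peak with a 20% plateau. The
absolute amplitudes are plausible placeholders (published curves are
normalized, so true amplitudes in degrees are not recoverable from
them); the *shape* difference between conditions matters because V(t) is
scale-free — two conditions differing only by a gain produce identical
V(t) and hence mi = 0 in the noise-free limit.

Each subject scales both kernels by a log-normal amplitude factor
(sdlog = 0.5). The infrared-like tracker (`ET`) adds 0.08° per-eye
Gaussian gaze noise and marks samples invalid with probability 0.2,
which under the 15-of-66 exclusion rule gives an analytic expected trial
exclusion of $1 - F_{\mathrm{Binom}(66,0.2)}(14) = 0.335$, matching the
~33% exclusion rate reported for such devices in this setting. The
webcam-like tracker (`WC`) adds larger noise (0.2°) and no validity
dropouts, mirroring how consumer webcam gaze estimation behaves: it
always returns an estimate, just a noisier one.

The generator inverts the analysis geometry exactly — eyes fixate a
point on the central normal whose depth subtends the simulated
$\gamma(t)$ — so with zero noise the analysis recovers the baseline to
$10^{-9}$ degrees. What it does **not** emulate: head movement (the task
is chin-rest-free; real head translation biases both eyes coherently),
blinks as structured gaps rather than independent per-sample dropouts,
saccades and fixational drift, pupil-size artifacts on infrared gaze
estimates, and any dependence of webcam noise on lighting. Passing tests
therefore demonstrate that the pipeline measures what it defines, not
that any particular device is this well behaved.

### Why amplitude recovery needs noise

Because V(t) is normalized per trial, a noise-free subject's $T$ is
independent of their response amplitude — the normalizer absorbs it. With
additive tracker noise the normalizer is inflated by the noise floor, so
higher-amplitude subjects retain proportionally more signal after
normalization and show larger $T$: amplitude becomes identifiable
through signal-to-noise ratio. The parameter-recovery check (Spearman
rank correlation between true amplitude factors and estimated $T$ across
28 subjects, ten fixed seeds) is run on the infrared-like tracker, whose
lower noise makes it the reference instrument; at webcam noise levels
the same correlation is present but weaker.

## Numerical choices

- **Grid anchoring.** The uniform grid is $k \cdot 1000/\mathrm{rate}$
  ms for integer $k$, so $t = 0$ (onset) is always a grid point and
  $V(0) = 0$ holds exactly. Window membership uses a $10^{-9}$ ms
  tolerance against floating-point grid endpoints.
- **Interpolation.** Linear, with clamped ends: grid points outside the
  span of valid timestamps take the nearest valid value rather than an
  extrapolated slope. Fewer than two valid samples exclude the trial
  ("insufficient data").
- **Flat trials.** A trial with zero excursion in the normalization
  window gets $V \equiv 0$ and `norm_max = 0`, keeping it in averages
  without dividing by zero.
- **Degenerate t-tests.** Two zero-variance samples with equal means
  return $t = 0, p = 1$ (and $\pm\infty, 0$ for unequal means) instead
  of erroring, so batch comparisons never abort on constant data.
- **Exclusion bookkeeping.** Segmentation conserves trials
  (retained + excluded = events); every exclusion carries a reason in
  the QC table, and subjects lacking retained trials in a condition get
  a reasoned missing mi rather than silently vanishing. Webcam-style
  recordings need no special-casing: their validity codes are all 0, so
  the exclusion rule is naturally inert for them.
- **Determinism.** All randomness flows through explicit seeds;
  datasets, results and reports contain no timestamps, so a rerun with
  the same seed is byte-identical.

## Problem sizes used by the test suite

The packaged checks run the full design where it is cheap — 28-subject
single-tracker cohorts across ten seeds for parameter recovery, a
1000-trial session for the normalization contract, 100 random small
instances for brute-force oracle equivalence — and small cohorts (2–4
subjects) for file round trips and end-to-end determinism. These sizes
are the package's validation choices; all are reproducible from the
fixed seeds in the tests.

## Limitations

Only horizontal vergence is analyzed; vertical coordinates are carried
through I/O but ignored. The eyes are modelled at $(\pm\mathrm{IPD}/2, 0)$
on the screen-centre normal, so head translation is treated as noise.
No blink or saccade detection is attempted beyond tracker validity
codes, no multiple-testing correction is applied to the comparison
report, and the simulator's amplitude defaults are placeholders, not
device calibrations.
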