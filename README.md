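# cogvergence

Quantifying **cognitive vergence** — the small, transient convergence of
the two eyes that follows an attended visual stimulus — from binocular
eye-tracking recordings of an oddball task. The package is aimed at
researchers analyzing event-locked vergence modulation as a marker of
stimulus processing (for example when comparing a consumer webcam gaze
tracker against an infrared research tracker), and at anyone who needs a
tested, reproducible reference pipeline for this measurement.

## The measurement

From each eye's on-screen gaze coordinate the pipeline computes the
azimuth of the line of sight and the vergence angle
γ = θ_L − θ_R (degrees); for symmetric fixation at distance *d* this
equals the closed form 2·atan(IPD / 2d). Per trial, responses are
summarized by the **relative vergence modulation**

    V(t) = (γ(t) − γ₀) / max |γ(t) − γ₀|,

with γ₀ the vergence at stimulus onset and the maximum taken over the
analysis window of the trial, making trials and devices comparable
regardless of absolute amplitude. Condition-averaged "mean V(t)" curves,
windowed response measures (initial 0–200 ms, peak 400–433 ms, delay
600–1250 ms) and the per-subject **modulation index**

    mi = (T − D) / (T + D)

— where T (D) is the mean 300–600 ms window-averaged response over
target (distractor) trials — quantify how much more the eyes converge
for rare targets than for frequent distractors. Preprocessing marks
samples with non-zero tracker validity codes (either eye) invalid,
discards trials with ≥ 15 invalid samples, and linearly interpolates
the rest onto an onset-anchored uniform grid.

A seedable simulator (`simulate_cohort()`) generates the whole design —
28 subjects, 100-trial sessions with 20% targets, 2000 ms mask +
2000 ms stimulus epochs, 30 Hz binocular sampling by an infrared-like
and a webcam-like tracker — with known ground-truth amplitudes, so every
stage of the pipeline is testable without access to human recordings.

## Worked example

```r
library(cogvergence)

params <- simulation_params(n_subjects = 4, seed = 42)
cohort <- simulate_cohort(params)
fit <- vergence_analysis(cohort)
fit
#> Cognitive-vergence analysis
#>   4 subject(s), tracker(s): ET, WC
#>   trials: 665 analyzed, 135 excluded (16.9%)
#>   ET: mean mi = 0.558 (SD 0.215, n = 4 defined, 100.0% positive)
#>   WC: mean mi = 0.826 (SD 0.259, n = 4 defined, 100.0% positive)

coef(fit)        # per-subject modulation indices
#>            ET        WC
#> S01 0.6065263 0.8909450
#> S02 0.5080789 0.5211225
#> S03 0.3002426 0.7538644
#> S04 0.8180171 1.1400248
```

All 135 excluded trials come from the infrared-like tracker's validity
dropouts (~34% of its trials, none for the webcam), each logged with a
reason in `fit$qc`. Every subject shows a positive modulation index with
both devices — targets drive stronger convergence than distractors — and
`summary(fit)` adds the window table (e.g. ET target peak 0.456 ± 0.324
vs distractor 0.159 ± 0.373 across trials), cross-tracker sign-agreement
counts and the two-tailed t-test report at trial and subject level.
`plot(fit)` draws the condition-averaged V(t) curves per tracker.

The same pipeline runs over CSV directories:

```r
run_simulate("data", simulation_params(seed = 1))   # gaze + event CSVs
run_analyze("data", "results")                      # curves, tables, tests
run_report("results")                               # results/report.md
```

or from a shell via `inst/scripts/cogverg.R`
(`Rscript cogverg.R all --out run1 --seed 1`).

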