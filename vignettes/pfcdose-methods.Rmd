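---
title: "pfcdose: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pfcdose: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the task and
study design it models, the generative model behind the synthetic data,
every tunable parameter with its default and why, the numerical
conventions the analyses rely on, and the choices made where the design
was genuinely open.  It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The study design being modeled

A subject performs a covert-attention task: a cue appears at one of four
screen quadrants for 363 ms while the subject fixates centrally; at cue
offset three distractors fill the remaining quadrants; after a delay drawn
uniformly from 585–1755 ms a Go signal (90° orientation change) occurs,
and on target trials the subject must saccade to the cued location within
a 250 ms response window.  Three trial types are randomly interleaved:
*target* (change in the target), *distractor* (change in the diagonally
opposite distractor; correct response is holding fixation) and
*target+distractor* (both change; saccade to the target).  Outcomes are
hit, fixation break (response before any Go signal — an impulsivity-type
error), saccade to distractor (distractibility-type), or no response.

Dosing follows a flanked block design: each tablet dose (defaults 2.5, 5,
6.25, 7.5, 10 mg; weight-based mg/kg obtained by half-up rounding to two
decimals) is given on three consecutive sessions, and each block is
preceded and followed by two placebo sessions, with consecutive blocks
sharing their flanks.  For `D` dose blocks with block size `b` and flank
size `f` the schedule has `f + D(b + f)` sessions — 27 sessions (15
treatment, 12 placebo) for the five-dose default.  The flanking placebo
sessions of a block are the matched control pool for everything computed
on that block (behavior, correlations, decoding), which controls for
slow, non-pharmacological drift.  Subjects are always analyzed separately.

## The generative model

Each neuron `i` fires as an inhomogeneous Poisson process with intensity

```
rate_i(t) = b_i * g_i(t)  +  l_i * z  +  e_i ,   clipped at 0,
```

where `b_i` is the baseline rate, `z ~ N(0,1)` is a single scalar latent
drawn once per trial and shared by all neurons, `l_i` its signed loading
(spikes/s per latent SD), and `e_i` optional independent per-trial jitter.
The gain `g_i(t)` is a product of epoch factors that are active only when
the relevant event involves the neuron's preferred quadrant:

* a **visual transient** spanning ±80 ms around `response_latency`
  (measured from cue onset for a cued preferred quadrant, or from
  distractor-array onset when a distractor occupies it) with factor
  `visual_gain`.  The parameter is the *time-to-peak*: an 160 ms box
  smoothed by the 30 ms analysis kernel peaks at its center with 99.2% of
  the full gain, so latency and gain are recovered by the peak metrics
  without deconvolution.
* a **sustained attention factor** from 500 ms post-cue until 50 ms
  before saccade onset (or until 250 ms post-change when no saccade
  occurs) with factor `attention_gain`.
* a **perisaccadic burst**, ±50 ms around saccade onset toward the
  preferred quadrant, with factor `saccade_gain`.

The three regimes are disjoint by construction (the attention regime ends
where the saccade burst begins).  This is deliberate: the response
metrics treat the epochs as separable, and a generator whose regimes
overlap would entangle the very parameters the recovery tests are
supposed to identify.  It is also the main idealization — real prefrontal
responses overlap their epochs freely.

Spike sampling is exact (piecewise-constant intensity: Poisson counts per
segment, uniform times within segments), so Fano-factor and correlation
properties follow from the model rather than from a discretized
approximation.

**Rank-1 latent.** One global scalar per trial is the simplest structure
that yields both signs of pairwise correlation (through signed loadings)
and the rising relationship between tuning similarity and noise
correlation (when loadings are coupled to the preferred quadrant, as
`make_ensemble(tuning_coupled_loadings = TRUE)` does).  For two neurons
with baselines `b` and loadings `l` counted over a window of `w` seconds,
the model-implied count correlation is `l²w² / (bw + l²w²)`; the test
suite verifies the generator against this closed form and against a
brute-force Poisson-mixture simulation to ±0.02.

**Defaults and their rationale.** Trial counts per session are normal
(mean 817, SD 93, truncated at 1), the per-session scale of a
well-trained subject working a ~2 h session.  Ensembles default to 48
neurons on 32 electrodes (so same-electrode pairs exist and exercise the
exclusion rule), ~70% of them tuned, baselines log-normal around
8 spikes/s, visual/saccade gains ~2–3, attention gains ~1.3–2, visual
time-to-peak 100–140 ms, latent loadings ~1.5 spikes/s — values in the
range a prefrontal recording would show, chosen once and not revisited.
The default hit probability is 0.72 with an error mix of 0.45 fixation
breaks, 0.30 distractor saccades, 0.25 no-responses.  A
`dose_effect_spec` multiplies attention gains, latent loadings and hit
probability per dose; its default (all 1) is the null study, under which
every generated quantity is distribution-identical across treatment
labels (verified by Kolmogorov–Smirnov tests in the suite).

**Seed policy.** Every source of randomness derives from a master seed
via `substream = (master * 10007 + index * 101) mod (2³¹ − 1)`, one
substream per session (and per permutation, per fold shuffle), so any
session is reproducible in isolation and the whole pipeline is
byte-deterministic.

## Analysis conventions that matter

* **Windows.** All counting windows are half-open `[start, end)` on a
  1-ms grid, which makes count additivity over adjacent windows exact.
  Canonical epochs: baseline `[-200, 0)` and cue `[0, 200)` re cue onset,
  attention `[600, 1000)` re cue onset, saccade `[-50, +50)` re saccade
  onset.
* **SDFs.** Unit-area Gaussian kernel, SD 30 ms, truncated at ±5 SD, zero
  padding outside the trial and no edge renormalization: the resulting
  negative bias is confined to ~150 ms borders that lie outside every
  analysis window, and the SDF integral equals the spike count to <1%.
* **Attention-metric window.** The sustained-response metrics use a
  400 ms window centered midway between cue offset and *saccade onset*,
  per trial.  (A fixed `[600, 1000)` epoch is also available and is what
  selectivity uses; which of the two definitions feeds population
  averages is genuinely ambiguous in this design's tradition, so both are
  implemented and the per-trial one feeds metrics 12–15.)  A consequence
  of the saccade-anchored window is that attention metrics are computed
  on hit trials, which carry a saccade time.
* **Fano factor.** Throughout, trial-to-trial variability is SD/mean (the
  coefficient of variation); a config switch (`fano_convention =
  "var_over_mean"`) restores the conventional variance/mean.  The CV
  default follows the metric definitions this pipeline reproduces;
  fidelity was preferred over convention.
* **Ratios and ties.** Ratio metrics are undefined (NA, logged) when the
  denominator falls below 0.1 spikes/s — clipping would manufacture
  numbers where the data carry none.  Peak ties break to the earliest
  time; preferred-quadrant ties break to the lowest quadrant index.
  Latencies are reported at 1-ms resolution.
* **Noise correlations.** Counts are z-scored within each cue-quadrant
  condition (mean and SD over that condition's trials) and pooled before
  the Pearson correlation — the standard construction for "correlation of
  the variability around the condition mean", and the one that makes the
  estimate invariant to per-neuron affine rate changes.  Conditions with
  fewer than 10 trials are dropped (estimator stability), zero-variance
  neurons are excluded and logged, same-electrode pairs are excluded.
  Pairs with r exactly 0 belong to neither sign stratum.  Target-only
  trials enter, matching the selectivity computation (whether error-trial
  types should enter is open; the choice is a config flag).
* **Decoding.** Features are standardized per fold with training-set
  statistics only; folds are label-stratified and seeded; the classifier
  is a one-vs-rest L2-regularized hinge-loss linear SVM trained by dual
  coordinate descent with C = 1 fixed (neither the regularization nor the
  solver is specified by the tradition this follows; both are fixed for
  reproducibility and configurable).  The permutation p value uses the
  +1 correction, `(1 + #{null ≥ obs}) / (N + 1)`, so it is never 0.
  Decoded labels: cue quadrant (cue epoch), attended quadrant (attention
  epoch), saccade-endpoint quadrant (saccade epoch); hit trials only by
  default, since error trials carry ambiguous attentional labels.
* **Multiple comparisons.** The dose scan's Bonferroni family is the
  declared grid of 19 metrics × subjects (38 for two subjects), not the
  count of tests that happened to be runnable; skipped tests are reported
  with reasons.  Significance is strict inequality at `alpha/m`.
* **Effect sizes.** η² = SS_between/SS_total accompanies every
  large-sample ANOVA (correlation and structure scans), because with
  thousands of pairs the p values saturate and only explained variance is
  interpretable.

## What a green test establishes — and what it does not

The synthetic generator reproduces the *statistical surface* the analyses
consume: Poisson counts with the right means per epoch/condition, a
controllable rank-1 correlation structure, realistic trial counts and
outcome mixes, and injected dose effects with known ground truth.  Green
recovery tests therefore establish that the pipeline measures what it
claims to measure (gains via metrics 9/14/18 within 10%, latents within
±0.02 of the closed form, selectivity false-positive rate at its nominal
α, permutation nulls at chance, Bonferroni family-wise error at its
nominal level).

They do not establish anything about real tissue: no bursting or
refractoriness, no higher-rank or time-structured co-fluctuations, no
overlap between epoch responses, no eye-movement artifacts, no
session-to-session electrode drift beyond what the flank design absorbs.
Null results on synthetic nulls are calibration checks, not re-analyses
of any experiment.

Two calibration details are worth naming.  The Kruskal–Wallis
false-positive rate on low-count Poisson data runs slightly conservative
(~0.9% at α = 1%), a known property of the chi-square approximation under
heavy ties; the acceptance test asserts the rate within ±2 binomial SEs
of α.  And the null-calibration replicates (family-wise error,
per-bin η²) are drawn at the statistical level — metric tables and pair
records sampled from the distributions the generator produces — because
200 spike-level studies would cost hours for no additional inferential
content; the spike-level null is verified separately by the KS
label-invariance and Poisson-dispersion tests.

## Open choices, resolved

* **Anti-preferred estimation.** The preferred/anti-preferred quadrants
  are the extremes of the mean epoch rate (the test determines
  selectivity; a point estimator still had to be chosen; the mean keeps
  continuity with the ratio metrics).  When only the preferred quadrant
  is modulated, "anti-preferred" is a three-way tie and its selected
  minimum is biased slightly low — a property of any extreme-picking
  estimator, visible as a few percent of upward bias in ratio metrics at
  200 trials/condition.  Recovery tests therefore assert medians across
  neurons.
* **Placebo in the dose factor.** The per-metric ANOVA includes placebo
  as a factor level alongside the doses (the dose axis of the reports
  plots placebo as its leftmost level).
* **Single-trial peak window (metric 8).** The same `[0, 200)` cue window
  as the trial-averaged peak.
* **Baseline-epoch tuning.** No tuning is measurable before stimulus
  onset, so visual (cue-epoch) tuning substitutes for the baseline epoch
  wherever a tuning assignment is needed.
* **Misses.** Hit rate counts every non-hit outcome as a miss
  (configurable to exclude no-responses from the denominator).
* **Config format.** Scenario files are JSON or a flat `key: value` text
  format parsed in-package; unknown keys are rejected by name.
* **Spike-time origin.** Trial times are 0-based at cue onset; spikes are
  *signed* offsets extending to −500 ms so the baseline epoch
  `[-200, 0)` has data.  (A strictly non-negative spike convention is
  incompatible with a pre-cue baseline epoch under a cue-onset origin.)
* **Scheduler scope.** The scheduler reproduces the flanked-block design
  exactly; odd session counts observed in real datasets (an extra
  treatment session beyond `D × b`) are not modeled.

## Known limitations

Attention metrics and decoding use hit trials only, so severely degraded
behavioral conditions shrink their trial base; the pipeline logs (rather
than imputes) everything it drops.  The permutation null retrains the
full cross-validated classifier per permutation — 1000 permutations on a
full session take tens of seconds, so the batch pipeline computes nulls
only on request (`decode_null = TRUE`).  The generator's dose effects act
multiplicatively on three parameters; richer pharmacology (time-course
within session, neuron-type specificity) is out of scope.
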