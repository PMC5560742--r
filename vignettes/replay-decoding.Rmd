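---
title: "Decoding working-memory replay from MEG sensor data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory replay: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the analysis it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the method left genuine freedom.

## The analysis model

The scientific question is whether the delay period of a sequential
working-memory task contains re-evocations ("replay") of the
category-specific sensor patterns elicited at encoding, and whether those
re-evocations have consequences for behavior. The package operationalizes
this as a chain of five stages.

**Encoding classification.** The single-trial evoked response is treated as
a spatio-temporal feature vector per 20 ms bin: 13 consecutive samples at
600 Hz for each of 274 channels, flattened channel-major into 3562 features.
Three pairwise linear support-vector machines (F–B, F–C, B–C; categories
ordered F < B < C, a positive margin favoring the pair's first member)
are cross-validated per bin over the 26 bins centered at −10..490 ms. The
assumptions are the standard ones of linear decoding: category information
is expressed as an (approximately) linearly separable shift of the sensor
pattern, and trials are exchangeable within category. Feature reduction is a
univariate two-sample t-test (p < 0.05) and normalization a per-feature
z-score; both are learned *inside each training fold only*, because either
one, fitted on all trials, leaks test information into the training state —
an automated test corrupts held-out rows and asserts the trained state is
unchanged.

**Delay-period state decoding.** The best encoding bin's classifiers slide
over the retention window (1000–4000 ms after the last stimulus offset,
which excludes the offset-evoked transient) and an equally long
intertrial-interval control window. Each 20 ms bin receives the label of the
pairwise decision with the largest absolute decision value, and that
absolute value is the bin's confidence `d`. This largest-|margin| rule is
the only combination rule consistent with picking "the class with the
largest distance to the decision boundaries"; the three margins are not
recalibrated across pairs because they share one training pipeline.

**The d\* rejection rule.** Decoding every bin forces a label even on noise.
The rule ties the rejection rate to the classifier's measured reliability:
if the selected bin's cross-validated accuracy is r, the (1 − r) least
confident retention-period bins are relabeled as the null state N. `d*` is
the lower empirical quantile (no interpolation) of the pooled
retention-period distances at probability 1 − r, so the rejected fraction is
rank-exact: with r = 0.78, exactly 22% of retention bins fall below `d*`.
The threshold is computed per subject over all retention bins pooled across
trials — per-trial thresholds are unstable at 150 bins — and the *same*
threshold is applied to the ITI, where a noise-dominated window then loses a
much larger fraction of bins. The reliability is taken as the mean-over-pairs
CV accuracy at the selected bin, exposed as `pipeline_config(reliability=)`
for sensitivity analyses.

**Replay dynamics.** Replay epochs are maximal runs of identical non-N
labels; lengths live in bin units internally and become ms only at
presentation (×20), so histogram edges are exact. The four canonical length
ranges are 20–140, 160–400, 420–1100 and 1200–3000 ms; assignment is by
upper edge, so the 20 ms-grid lengths 1120–1180 ms that fall between the
printed edges are counted with the longest range, consistent with the
> 1100 ms long-replay rule. Transition matrices are estimated from
within-trial bin pairs only — counting across trials would fabricate
transitions across multi-second gaps. N is a full Markov state (transitions
to and from N are counted), while the forward/backward directionality
products use only the three stimulus states after remapping categories to
their sequence positions: forward = p(1→2)·p(2→3)·p(3→1), backward =
p(3→2)·p(2→1)·p(1→3). All retention-vs-ITI and directional comparisons use
two-sided Wilcoxon rank-sum tests, exact for group sizes ≤ 10 without ties
and tie-corrected normal approximation otherwise; the epoch-histogram
comparisons use the same test for uniformity, a choice the method left open.

**Predominance, behavior, ERFs.** "Predominantly maintained" (PM) is
operationalized as the category with the most decoded retention bins, ties
broken by longest single epoch, then earliest occurrence; the
longest-single-epoch alternative sits behind `rule = "longest"` and reports
name the rule used. Whether PM depends on category or sequence position is
tested with a within-subject category × position ANOVA on per-subject PM
proportions. The behavior link is a linear mixed-effects model (REML,
random subject intercept) of each outcome on the probe's longest replay
duration; binary accuracy is modeled on the 0/1 scale to keep the
coefficient in probability-per-ms units, with a logistic variant behind
`family = "binomial"`. A singular random-intercept fit falls back to pooled
regression with a warning. The ERF contrast compares each subject's mean
encoding response for PM versus non-PM stimuli (disjoint trial sets) after
20 Hz low-pass and whole-epoch baseline; group inference is a pointwise
paired F statistic with familywise error controlled by sign-flip
max-cluster-mass permutation over spatio-temporal clusters, using a channel
adjacency graph. The same permutation scheme (in 1-D) corrects the encoding
accuracy curves. Cluster permutation replaces parametric random-field
correction throughout: it requires only within-subject exchangeability of
condition labels, needs no smoothness estimate, and every report labels the
method explicitly.

## Parameters of the synthetic generator

The generator (`sim_params()`) defines the study conditions all tests run
under. Its defaults were fixed once, from the task structure and from what
is typical for evoked MEG responses:

| parameter | default | units | rationale |
|---|---|---|---|
| `n_channels` | 274 | — | axial gradiometer array size |
| `fs` | 600 | Hz | acquisition rate |
| `evoked_peak_ms` / `evoked_width_ms` | 170 / 40 | ms | category-discriminative component at the selected bin latency |
| `early_peak_ms` / `early_width_ms` | 125 / 30 | ms | early visual component carrying the attention effect |
| `snr_encoding` | 1.2 | × noise SD | yields realistically imperfect (above-chance, sub-ceiling) CV accuracy |
| `snr_replay` | 2 | × noise SD | replayed patterns are recoverable but fragmented by the d\* rule |
| `noise_sd` | 1e-13 | T | sensor noise scale; makes the 1.5e-11 T artifact threshold ~150 SD |
| `attention_gain_pm` | 0.7 | — | PM stimuli receive a reduced early component; 1 disables the effect |
| `hidden_transition` | sticky 4-state chain | — | p(S1→S1) = 0.97 so the predominant stimulus produces multi-hundred-ms epochs, some > 1100 ms |
| `iti_transition` | N-dominated chain | — | the control window is mostly null state |
| `behavior_slope` | 0.001 | logit/ms | hit odds rise with the probe's longest replay |
| `pattern_seed` | `NULL` | — | share one sensor topography across a cohort (see below) |

Two generator choices deserve emphasis. First, the hidden replay process is
a *first-order Markov chain* over {S1, S2, S3, N} — not a claim about the
brain, but the process under which the count-based estimators downstream
are well-defined and their recovery testable. Under the default `"pm"`
mapping, chain state S1 is mapped to the stimulus at a uniformly random
sequence position per trial, so predominance is position- and
category-balanced by construction. Second, `pattern_seed`: spatial category
patterns and the early-component topography are drawn per seed, so giving
each simulated subject an independent seed would give each a different
topography and group-level ERF statistics (which average cell-by-cell across
subjects) would see effects cancel. Real cohorts share broadly consistent
sensor topographies; setting one `pattern_seed` per cohort (the pipeline
derives it from the config seed) emulates that, while noise, hidden states,
and behavior remain subject-specific.

What the generator does **not** emulate: 1/f and physiological noise
spectra, channel covariance (white Gaussian noise per channel is the
simplest model under which the classifiers' assumptions hold; a covariance
hook is the natural extension), eye-blink or cardiac artifacts beyond
amplitude outliers, head movement, perspective-specific pattern variation
(perspective is metadata only, as the analysis decodes category
irrespective of it), and any source-space structure. Passing tests
therefore show the *estimators* are correct and calibrated under their
assumptions — not that real recordings satisfy those assumptions.

## Numerical choices

- **Filtering** is zero-phase (forward–backward) Butterworth via `signal`,
  with odd-reflection edge padding; the downstream analyses are
  timing-sensitive and phase distortion would shift decoded latencies. The
  notch is a band-stop of order 5 with ±2 Hz half-width (only the center
  frequency and order are dictated by the acquisition setup).
- **Cropping** is half-open `[start, end)` so abutting windows never share
  samples; a 20 ms *analysis bin*, by contrast, spans both edges (13 samples
  at 600 Hz). Encoding epochs are therefore simulated on −100..500 ms
  *inclusive* (361 samples) so the 490 ms-centered bin has its full sample
  count.
- **Retention windows**: 150 bins per 3000 ms window (= 3000/20); the
  alternative 151-bin reading (counting shared-edge bins) is noted but not
  used.
- **Quantiles** for `d*` use the lower empirical order statistic with a
  1e-6 rank epsilon so integer targets like 0.22 × 10000 are hit exactly in
  floating point.
- **Ties**: best-bin selection takes the earliest maximum; the
  zero-margin decode falls to the pair's first category under F < B < C;
  predominance ties use the documented chain.
- **SVM cost** defaults to 1 (the implementation standard; the method
  specifies no regularization constant) and is exposed. The selected-bin
  classifiers applied to the delay are refit on all encoding trials, the
  natural choice when the CV estimate is only used to pick the bin and set
  the reliability.
- **Degenerate inputs** error early and specifically: non-stochastic
  generators, unbalanced training classes, single-class feature reduction,
  empty crop windows, subjects missing replay groups (excluded and listed),
  and subjects whose position rows were never visited (excluded per
  comparison and logged).

## Problem sizes in the test suite

The automated tests run the full machinery at reduced scale, chosen so the
whole suite completes in minutes while every statistical check retains its
power: 16–32 channels in simulation-heavy tests (274 only where the feature
geometry itself is asserted), full 162-trial designs where the design
matters and 27–54-trial subsets elsewhere, 100–200 replicate datasets for
calibration and power checks, and 200–500 permutations for cluster tests
(5000 remains the analysis default). The end-to-end determinism check runs
the complete pipeline twice at small scale and compares file checksums.

## Known limitations

- Sensor-level only; no source localization, forward modeling, or
  anatomical statistics.
- The decoded-state analysis is count-based on hard labels; no
  hidden-Markov emission model is fit, so measurement noise in the labels
  biases transition estimates toward the observed, not the generating,
  process (visible in the fragmentation of long replay epochs by the d\*
  rule).
- Margins are not calibrated across the three pairwise classifiers; the
  d\* rule assumes their distance scales are comparable.
- The linear treatment of binary accuracy in the mixed model is faithful to
  the method it implements but heteroscedastic by construction; the
  logistic variant is preferable when the coefficient itself matters.
- Real-data quantities that depend on the recordings themselves (peak
  accuracies, d\* values, transition probabilities) are not reproduction
  targets; only rule-forced quantities (bin counts, window sizes, rejection
  fractions) are.
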