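# megreplay

Decoding which stimulus is replayed during working-memory retention, from
multichannel MEG sensor data.

In a sequential working-memory (Sternberg-style) task, three visual stimuli —
a face (F), a banana (B), and a chair (C), each from one of three viewing
perspectives — are encoded one after another, held over a 5000 ms delay, and
probed. `megreplay` implements the sensor-level analysis chain that asks
whether, and for how long, the category-specific activity patterns evoked at
encoding are *re-evoked* ("replayed") during the delay, how that replay
unfolds dynamically, and whether it matters for memory. Because no raw
recordings from such a study are publicly deposited, the package ships a
first-class synthetic-data generator that emulates the recording (274
sensors, 600 Hz), the 162-trial design, the evoked responses, a hidden
4-state Markov replay process, and the replay–behavior coupling, so every
stage is testable end to end.

It is aimed at cognitive neuroscientists who want a scrutable, fully tested
reference implementation of this family of delay-period decoding analyses.

## The method

1. **Encoding classifiers.** Epochs (−100..500 ms around each stimulus
   onset; 50 Hz notch, >1.5e-11 T artifact rejection) are windowed into
   20 ms bins (13 samples × 274 channels = 3562 features per bin; 26 bins
   centered −10..490 ms). Per bin, three pairwise linear SVMs (F–B, F–C,
   B–C) are trained with per-fold z-scoring and univariate t-test feature
   reduction (p < 0.05), and scored by stratified 10-fold cross-validation
   on class-balanced trials. Group-level significance of the accuracy curve
   versus chance (50%) is assessed by one-sample t statistics with
   familywise-error control by sign-flip max-cluster-mass permutation. The
   bin with the highest mean accuracy (typically ~170 ms) is selected.

2. **Delay-period state decoding.** The selected-bin classifiers slide over
   the 150 twenty-ms bins of the retention window (1000–4000 ms after the
   last stimulus offset) and of a 3000 ms intertrial-interval (ITI) control
   window. Each bin gets the label of the pairwise decision with the largest
   absolute margin, `d`. A confidence threshold `d*` is set as the empirical
   `(1 − reliability)` quantile of the retention-period distances, with
   reliability the selected-bin CV accuracy: if the classifier is reliable
   78% of the time, the least-confident 22% of retention bins are relabeled
   as the null state N. The same `d*` is applied to the ITI.

3. **Replay dynamics.** Maximal runs of identical non-N labels are replay
   epochs; their length histograms (20–140, 160–400, 420–1100, 1200–3000 ms)
   and counts are compared between retention and ITI with two-sided Wilcoxon
   rank-sum tests. A 4-state (F/B/C/N) discrete-time Markov transition matrix
   is estimated from within-trial bin-to-bin transitions. After remapping
   categories to sequence positions, forward replay `p(1→2)·p(2→3)·p(3→1)`
   is compared with backward `p(3→2)·p(2→1)·p(1→3)`, plus the three row-wise
   directional comparisons.

4. **Predominance, behavior, ERFs.** The predominantly maintained (PM)
   category of a trial is the one with the most decoded retention bins. A
   linear mixed-effects model (random subject intercept) relates the probe's
   longest replay epoch to memory accuracy and response time; probes grouped
   as none / short (≤1100 ms) / long (>1100 ms) feed a repeated-measures
   ANOVA with paired post hoc t tests. Finally, encoding ERFs (20 Hz
   low-pass, whole-epoch baseline) of PM versus non-PM stimuli are contrasted
   with a spatio-temporal cluster-mass permutation over a sensor adjacency
   graph.

## Worked example

A single simulated subject, end to end (32 sensors to keep it quick):

```r
library(megreplay)

params <- sim_params(n_channels = 32, snr_encoding = 1, seed = 42)
design <- assign_predominant(enumerate_design(42), params)
encoding <- baseline_correct(notch_filter(simulate_encoding_epochs(design, params)))

grid <- make_time_bins()              # 26 bins, centers -10..490 ms
curve <- crossvalidate_bins(encoding, grid, folds = 10, seed = 1)
print(curve)
#> <accuracy_curve> 26 bins, 10-fold CV; peak mean accuracy 88.6% at 170 ms

best <- select_best_bin(curve)
classifiers <- train_bin_classifiers(encoding, best$bin_center_ms, grid, seed = 1)

states  <- simulate_hidden_state_sequence(design, params, "retention")
delay   <- simulate_delay_epochs(design, states, params, "retention")
windows <- define_analysis_windows()
decoded <- decode_period(classifiers, delay, windows$retention, "retention")
thr     <- compute_rejection_threshold(as.vector(decoded$d), best$mean_accuracy)
decoded <- apply_threshold(decoded, thr)
print(decoded)
#> <decoded_sequences> retention: 162 trials x 150 bins; 11.4% rejected as N (d* = 1.86)

print(histogram_epoch_lengths(extract_replay_epochs(decoded)))
#> <epoch_length_histogram> epochs per length range (ms):
#>    20-140   160-400  420-1100 1200-3000
#>      1917       588       277        22

print(estimate_transition_matrix(decoded))
#> <transition_matrix> states F/B/C/N, 24138 transitions
#>       F     B     C     N
#> F 0.879 0.043 0.021 0.057
#> B 0.049 0.856 0.022 0.073
#> C 0.025 0.022 0.893 0.061
#> N 0.156 0.204 0.149 0.492

pred <- summarize_predominance(decoded, design)
mean(pred$pm_category == design$pm_category, na.rm = TRUE)
#> [1] 0.975
```

Reading the output: the classifiers peak at the 170 ms bin (88.6% CV
accuracy at this simulation's signal-to-noise ratio), so the 170 ms
classifiers decode the delay. Their CV accuracy sets the rejection rule
(here 88.6% reliable, so 11.4% of retention bins are relabeled N, with the
margin threshold d\* = 1.86). Decoded states are strongly sticky — large
diagonal transition probabilities, exactly the signature the replay-epoch
analysis quantifies — and the trial's predominantly maintained category
matches the generator's ground truth on 97.5% of trials.

The multi-subject chain (group cluster statistics, directionality tests,
mixed-effects behavior model, PM vs non-PM ERF contrast) is run by

```r
res <- run_pipeline(pipeline_config(n_subjects = 14, seed = 1, out_dir = "out"))
```

which writes result tables, the configuration, and a checksum manifest;
runs with the same configuration and seed are byte-identical.

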