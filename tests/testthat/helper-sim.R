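# Shared small-scale fixtures; all generated in code at test time.

quick_params <- function(n_channels = 24L, ...) {
  sim_params(n_channels = n_channels, ...)
}

# Noise-only epochs with a given geometry.
noise_epochs <- function(n_trials = 4, n_channels = 8, n_samples = 61,
                         fs = 600, t0 = -100, seed = 42) {
  set.seed(seed)
  sensor_epochs(array(rnorm(n_trials * n_channels * n_samples, sd = 1e-13),
                      dim = c(n_trials, n_channels, n_samples)),
                t0 + (seq_len(n_samples) - 1) * 1000 / fs, fs,
                "stimulus_onset",
                data.frame(trial_id = seq_len(n_trials)))
}

# Epochs holding one pure sinusoid on every channel of every trial.
sine_epochs <- function(freq_hz, fs = 600, dur_ms = 2000, n_channels = 2) {
  t_ms <- seq(0, dur_ms, by = 1000 / fs)
  x <- sin(2 * pi * freq_hz * t_ms / 1000)
  dat <- aperm(array(x, dim = c(length(t_ms), 1, n_channels)), c(2, 3, 1))
  sensor_epochs(dat, t_ms, fs, "stimulus_onset", data.frame(trial_id = 1L))
}

# RMS over the central half of the samples (avoids filter edge transients).
central_rms <- function(epochs) {
  n <- length(epochs$time_ms)
  idx <- seq(floor(n / 4), ceiling(3 * n / 4))
  sqrt(mean(epochs$data[, , idx]^2))
}

# Hand-built linear scorer: one pairwise_classifier per pair reading a single
# feature of a length-3 input, with unit weight, so decision values equal the
# raw feature values.
toy_classifiers <- function() {
  mk <- function(pair, feature) {
    mask <- rep(FALSE, 3); mask[feature] <- TRUE
    structure(list(pair = pair, bin_center_ms = 170, feature_mask = mask,
                   center = rep(0, 3), scale = rep(1, 3),
                   weights = 1, bias = 0, cost = 1, alpha = 0.05),
              class = "pairwise_classifier")
  }
  list("F-B" = mk(c("F", "B"), 1), "F-C" = mk(c("F", "C"), 2),
       "B-C" = mk(c("B", "C"), 3))
}
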