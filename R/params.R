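#' Simulation parameters
#'
#' Bundles every knob of the synthetic MEG generator. Defaults emulate the
#' recording and task conditions the analysis assumes: a 274-channel sensor
#' array sampled at 600 Hz, category-specific evoked responses peaking at
#' 170 ms after stimulus onset, a shared early visual component peaking at
#' 125 ms whose amplitude is reduced (attention gain < 1) for the stimulus
#' that will dominate the retention period, a sticky 4-state hidden Markov
#' replay process during retention, an intertrial interval that is almost
#' entirely the null state, and a behavioral hit probability that increases
#' with the length of the probe's longest replay epoch.
#'
#' @param n_channels Number of sensors (default 274).
#' @param fs Sampling rate, Hz (default 600).
#' @param evoked_peak_ms Latency of the category-specific evoked peak, ms.
#' @param evoked_width_ms Gaussian SD of the evoked temporal kernel, ms.
#' @param early_peak_ms Latency of the shared early visual component, ms.
#' @param early_width_ms Gaussian SD of the early component, ms.
#' @param snr_encoding Evoked peak amplitude in units of the sensor noise SD.
#' @param snr_replay Replayed-pattern amplitude in units of the noise SD.
#' @param noise_sd Per-sample sensor noise SD, tesla.
#' @param attention_gain_pm Multiplier (< 1) on the early component of the
#'   to-be-predominant stimulus; 1 disables the effect.
#' @param hidden_transition 4x4 row-stochastic generator over hidden states
#'   (state 1 is mapped to the predominant stimulus, states 2-3 to the other
#'   sequence positions, state 4 is the null state N).
#' @param hidden_start Start distribution over the 4 hidden states.
#' @param iti_transition,iti_start Generator and start distribution for the
#'   intertrial interval (defaults dwell in N).
#' @param state_map `"pm"` maps hidden state 1 to the trial's predominant
#'   stimulus; `"position"` maps states 1-3 to sequence positions directly.
#' @param max_pattern_cos Upper bound on pairwise |cosine| between category
#'   patterns.
#' @param behavior_slope Change in detail-test hit log-odds per ms of the
#'   probe's longest replay epoch.
#' @param behavior_intercept Baseline detail-test hit log-odds.
#' @param order_accuracy Replay-independent order-test accuracy.
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (log ms).
#' @param rt_replay_coef Coefficient of replay length (ms) on log RT.
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param pattern_seed Optional separate seed for the spatial (channel-space)
#'   patterns. Giving every subject of a simulated cohort the same
#'   `pattern_seed` but different `seed`s emulates the group-consistent
#'   sensor topography that group-level ERF statistics rely on, while noise,
#'   hidden states, and behavior stay subject-specific. `NULL` derives the
#'   patterns from `seed`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_channels = 274L, fs = 600, evoked_peak_ms = 170,
                       evoked_width_ms = 40, early_peak_ms = 125,
                       early_width_ms = 30, snr_encoding = 1.2,
                       snr_replay = 2, noise_sd = 1e-13,
                       attention_gain_pm = 0.7,
                       hidden_transition = default_hidden_transition(),
                       hidden_start = c(0.30, 0.10, 0.10, 0.50),
                       iti_transition = default_iti_transition(),
                       iti_start = c(0.01, 0.01, 0.01, 0.97),
                       state_map = c("pm", "position"),
                       max_pattern_cos = 0.3,
                       behavior_slope = 0.001, behavior_intercept = 0.5,
                       order_accuracy = 0.75,
                       rt_meanlog = log(900), rt_sdlog = 0.3,
                       rt_replay_coef = 0, seed = 1L, pattern_seed = NULL) {
  state_map <- match.arg(state_map)
  p <- list(n_channels = as.integer(n_channels), fs = fs,
            evoked_peak_ms = evoked_peak_ms, evoked_width_ms = evoked_width_ms,
            early_peak_ms = early_peak_ms, early_width_ms = early_width_ms,
            snr_encoding = snr_encoding, snr_replay = snr_replay,
            noise_sd = noise_sd, attention_gain_pm = attention_gain_pm,
            hidden_transition = hidden_transition, hidden_start = hidden_start,
            iti_transition = iti_transition, iti_start = iti_start,
            state_map = state_map, max_pattern_cos = max_pattern_cos,
            behavior_slope = behavior_slope,
            behavior_intercept = behavior_intercept,
            order_accuracy = order_accuracy, rt_meanlog = rt_meanlog,
            rt_sdlog = rt_sdlog, rt_replay_coef = rt_replay_coef,
            seed = as.integer(seed),
            pattern_seed = if (!is.null(pattern_seed)) as.integer(pattern_seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$fs <= 0) stopf("fs must be positive")
  if (p$snr_encoding < 0 || p$snr_replay < 0) stopf("snr must be nonnegative")
  check_stochastic_matrix(p$hidden_transition, "hidden_transition")
  check_stochastic_matrix(p$iti_transition, "iti_transition")
  invisible(p)
}

check_stochastic_matrix <- function(P, name = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != 4L || ncol(P) != 4L) {
    stopf("%s must be a 4x4 matrix", name)
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stopf("%s rows must be nonnegative and sum to 1", name)
  }
  invisible(P)
}

#' Default retention-period hidden-state generator
#'
#' A sticky chain in which the predominant stimulus state (state 1) has a
#' 0.97 self-transition probability, producing the long replay epochs (often
#' exceeding 1100 ms) the retention analysis quantifies, while the other two
#' stimuli replay only briefly and the null state is visited in between.
#'
#' @return A 4x4 row-stochastic matrix (states 1, 2, 3, N).
#' @export
default_hidden_transition <- function() {
  matrix(c(0.97, 0.005, 0.005, 0.02,
           0.04, 0.88,  0.02,  0.06,
           0.04, 0.02,  0.88,  0.06,
           0.12, 0.03,  0.03,  0.82),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("S1", "S2", "S3", "N"), c("S1", "S2", "S3", "N")))
}

#' @rdname default_hidden_transition
#' @export
default_iti_transition <- function() {
  matrix(c(0.20, 0.01, 0.01, 0.78,
           0.01, 0.20, 0.01, 0.78,
           0.01, 0.01, 0.20, 0.78,
           0.01, 0.01, 0.01, 0.97),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("S1", "S2", "S3", "N"), c("S1", "S2", "S3", "N")))
}
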