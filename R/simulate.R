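# Synthetic sensor, hidden-state, and behavioral data generation.

gauss_kernel <- function(t_ms, peak_ms, width_ms) {
  k <- exp(-0.5 * ((t_ms - peak_ms) / width_ms)^2)
  k[t_ms < 0] <- 0  # evoked response starts at stimulus onset
  k
}

#' Simulate category-specific sensor patterns
#'
#' Draws one unit-norm channel-space vector per stimulus category (F, B, C)
#' with pairwise |cosine similarity| below `max_pattern_cos`, by rejection
#' sampling of Gaussian random directions. Deterministic given the seed.
#'
#' @param params A [sim_params] object.
#' @return A `n_channels x 3` matrix with columns `F`, `B`, `C`.
#' @export
simulate_category_patterns <- function(params) {
  if (params$n_channels < 3L) stopf("n_channels must be >= 3")
  with_seed(derive_seed(params$pattern_seed %||% params$seed, 1L), {
    for (i in 1:10000) {
      m <- matrix(stats::rnorm(params$n_channels * 3L), ncol = 3L)
      m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
      cc <- abs(crossprod(m))
      if (max(cc[upper.tri(cc)]) <= params$max_pattern_cos) {
        colnames(m) <- CATEGORY_LEVELS
        return(m)
      }
    }
    stopf("could not draw patterns with pairwise |cos| <= %g in %d channels",
          params$max_pattern_cos, params$n_channels)
  })
}

# Spatial pattern of the shared early visual component (not category-specific).
early_component_pattern <- function(params) {
  with_seed(derive_seed(params$pattern_seed %||% params$seed, 2L), {
    v <- stats::rnorm(params$n_channels)
    v / sqrt(sum(v^2))
  })
}

#' Assign the to-be-predominant stimulus of each trial
#'
#' Picks, uniformly at random among the three sequence positions, the stimulus
#' that will dominate the retention period. Adds `pm_position` and
#' `pm_category` columns; a design that already carries them is returned
#' unchanged so encoding and delay simulations stay consistent.
#'
#' @param design Trial design from [enumerate_design()].
#' @param params A [sim_params] object (its seed drives the assignment).
#' @return The design with `pm_position` and `pm_category` columns.
#' @export
assign_predominant <- function(design, params) {
  if (!is.null(design$pm_position)) return(design)
  with_seed(derive_seed(params$seed, 3L), {
    design$pm_position <- sample(1:3, nrow(design), replace = TRUE)
  })
  design$pm_category <- vapply(seq_len(nrow(design)), function(i)
    trial_sequence(design, i)[design$pm_position[i]], character(1))
  design
}

#' Simulate encoding-period epochs
#'
#' Generates one epoch per presented stimulus (three per trial) on a
#' -100..500 ms axis (inclusive of both edges so every 20 ms analysis bin up
#' to the 490 ms center has its full sample count). The signal is the
#' stimulus category's sensor pattern modulated by a Gaussian temporal kernel
#' peaking at `evoked_peak_ms`, plus a shared early visual component peaking
#' at `early_peak_ms`, both scaled by `snr_encoding * noise_sd`, in white
#' Gaussian sensor noise. The early component of the trial's to-be-predominant
#' stimulus is multiplied by `attention_gain_pm`.
#'
#' @param design Trial design (predominance assigned if absent).
#' @param params A [sim_params] object.
#' @return A [sensor_epochs] object aligned to `stimulus_onset`, whose
#'   `trial_meta` has one row per stimulus with `trial_id`, `stim_position`,
#'   `category`, `perspective`, and `is_pm`.
#' @export
simulate_encoding_epochs <- function(design, params) {
  if (nrow(design) == 0L) stopf("design must be nonempty")
  design <- assign_predominant(design, params)
  patterns <- simulate_category_patterns(params)
  early <- early_component_pattern(params)
  step <- 1000 / params$fs
  time_ms <- seq(-100, 500, by = step)
  n_s <- length(time_ms)
  meta <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    data.frame(trial_id = design$trial_id[i], stim_position = 1:3,
               category = trial_sequence(design, i),
               perspective = c(design$persp_1[i], design$persp_2[i],
                               design$persp_3[i]),
               is_pm = design$pm_position[i] == 1:3,
               stringsAsFactors = FALSE)
  }))
  n_e <- nrow(meta)
  amp <- params$snr_encoding * params$noise_sd
  k_cat <- gauss_kernel(time_ms, params$evoked_peak_ms, params$evoked_width_ms)
  k_early <- gauss_kernel(time_ms, params$early_peak_ms, params$early_width_ms)
  dat <- with_seed(derive_seed(params$seed, 4L), {
    arr <- array(stats::rnorm(n_e * params$n_channels * n_s, sd = params$noise_sd),
                 dim = c(n_e, params$n_channels, n_s))
    for (e in seq_len(n_e)) {
      gain <- if (meta$is_pm[e]) params$attention_gain_pm else 1
      sig <- amp * (outer(patterns[, meta$category[e]], k_cat) +
                      gain * outer(early, k_early))
      arr[e, , ] <- arr[e, , ] + sig
    }
    arr
  })
  sensor_epochs(dat, time_ms, params$fs, "stimulus_onset", meta)
}

#' Sample many first-order Markov chains at once
#'
#' @param n_chains Number of independent chains.
#' @param n_steps Chain length.
#' @param P Row-stochastic transition matrix.
#' @param start Start-state distribution.
#' @param seed Integer seed.
#' @return An `n_chains x n_steps` integer matrix of state indices.
#' @export
sample_markov_chains <- function(n_chains, n_steps, P, start, seed) {
  check_stochastic_matrix(P)
  cp <- t(apply(P, 1, cumsum))
  with_seed(seed, {
    s <- matrix(0L, n_chains, n_steps)
    s[, 1] <- sample.int(nrow(P), n_chains, replace = TRUE, prob = start)
    if (n_steps > 1L) for (t in 2:n_steps) {
      u <- stats::runif(n_chains)
      s[, t] <- 1L + rowSums(u > cp[s[, t - 1L], , drop = FALSE])
    }
    s
  })
}

#' Simulate hidden replay-state sequences
#'
#' Samples, per trial, a first-order Markov chain over the four replay states
#' (three stimuli + null N), one state per 20 ms bin of the analysis window.
#' Abstract chain states 1-3 are remapped to that trial's stimulus categories:
#' under `state_map = "pm"` state 1 becomes the trial's predominant stimulus
#' (so a sticky state 1 makes that category dominate); under `"position"`
#' states 1-3 are sequence positions 1-3 directly.
#'
#' @param design Trial design (predominance assigned if absent).
#' @param params A [sim_params] object.
#' @param period `"retention"` (uses `hidden_transition`) or `"iti"`
#'   (uses `iti_transition`, which dwells in N).
#' @param n_bins Number of 20 ms bins per trial (default 150, the 3000 ms
#'   analysis window).
#' @return A `n_trials x n_bins` character matrix over `{F,B,C,N}` with
#'   `trial_id` row names.
#' @export
simulate_hidden_state_sequence <- function(design, params,
                                           period = c("retention", "iti"),
                                           n_bins = 150L) {
  period <- match.arg(period)
  design <- assign_predominant(design, params)
  P <- if (period == "retention") params$hidden_transition else params$iti_transition
  start <- if (period == "retention") params$hidden_start else params$iti_start
  idx <- sample_markov_chains(nrow(design), n_bins, P, start,
                              derive_seed(params$seed, if (period == "retention") 5L else 6L))
  labels <- matrix("N", nrow(design), n_bins)
  for (i in seq_len(nrow(design))) {
    seq_cats <- trial_sequence(design, i)
    cats <- if (params$state_map == "pm") {
      c(seq_cats[design$pm_position[i]],
        seq_cats[setdiff(1:3, design$pm_position[i])])
    } else seq_cats
    labels[i, ] <- c(cats, "N")[idx[i, ]]
  }
  rownames(labels) <- design$trial_id
  labels
}

#' Simulate delay-period epochs from hidden states
#'
#' Builds retention-period (or intertrial-interval) sensor data in which every
#' 20 ms bin labeled F/B/C contains the matching category pattern at amplitude
#' `snr_replay * noise_sd` and N bins contain noise only. The retention axis
#' covers 1000..4000 ms after the offset of the last stimulus; the ITI axis
#' covers -3000..0 ms relative to the first stimulus onset. Both include the
#' closing edge sample so all 150 bins carry 13 samples.
#'
#' @param design Trial design.
#' @param states Hidden-state label matrix from
#'   [simulate_hidden_state_sequence()].
#' @param params A [sim_params] object.
#' @param period `"retention"` or `"iti"`.
#' @return A [sensor_epochs] object.
#' @export
simulate_delay_epochs <- function(design, states, params,
                                  period = c("retention", "iti")) {
  period <- match.arg(period)
  if (nrow(states) != nrow(design)) stopf("states not aligned to design")
  patterns <- simulate_category_patterns(params)
  n_bins <- ncol(states)
  step <- 1000 / params$fs
  spb <- floor(20 * params$fs / 1000)  # samples advanced per 20 ms bin
  n_s <- n_bins * spb + 1L
  t0 <- if (period == "retention") 1000 else -3000
  time_ms <- t0 + (seq_len(n_s) - 1L) * step
  align <- if (period == "retention") "last_stimulus_offset" else "first_stimulus_onset"
  # sample k (1-based) belongs to bin ceil(k/spb), capped at n_bins
  bin_of_sample <- pmin(ceiling(seq_len(n_s) / spb), n_bins)
  amp <- params$snr_replay * params$noise_sd
  dat <- with_seed(derive_seed(params$seed, if (period == "retention") 7L else 8L), {
    arr <- array(stats::rnorm(nrow(design) * params$n_channels * n_s,
                              sd = params$noise_sd),
                 dim = c(nrow(design), params$n_channels, n_s))
    for (i in seq_len(nrow(design))) {
      lab <- states[i, bin_of_sample]
      on <- lab != "N"
      if (any(on)) {
        arr[i, , on] <- arr[i, , on] + amp * patterns[, lab[on], drop = FALSE]
      }
    }
    arr
  })
  meta <- design[, intersect(c("trial_id", "run_id", "cat_1", "cat_2", "cat_3",
                               "pm_position", "pm_category"), names(design))]
  rownames(meta) <- NULL
  sensor_epochs(dat, time_ms, params$fs, align, meta)
}

# Longest run of `target` in a label vector, in bins (0 if absent).
longest_run_bins <- function(labels, target) {
  r <- rle(labels)
  hit <- r$values == target
  if (!any(hit)) 0L else max(r$lengths[hit])
}

#' Simulate behavioral responses
#'
#' Fills the design's response slots. The detail (item-memory) response is
#' correct with probability
#' `plogis(behavior_intercept + behavior_slope * replay_ms)`, where
#' `replay_ms` is the longest consecutive replay of the probe's category in
#' the trial's hidden retention states (20 ms per bin). The order response is
#' correct with a replay-independent probability; response times are
#' lognormal with an optional replay-length coefficient on the log scale.
#'
#' @param design Trial design.
#' @param states Retention hidden-state matrix aligned to the design.
#' @param params A [sim_params] object.
#' @return The design with `detail_response`, `detail_rt`, `order_response`,
#'   `order_rt` filled and the generative covariate `probe_replay_ms` added.
#' @export
simulate_behavior <- function(design, states, params) {
  if (nrow(states) != nrow(design)) stopf("states not aligned to design")
  n <- nrow(design)
  replay_ms <- vapply(seq_len(n), function(i)
    20 * longest_run_bins(states[i, ], design$probe_category[i]), numeric(1))
  with_seed(derive_seed(params$seed, 9L), {
    p_hit <- stats::plogis(params$behavior_intercept +
                             params$behavior_slope * replay_ms)
    design$detail_response <- stats::runif(n) < p_hit
    order_correct <- stats::runif(n) < params$order_accuracy
    design$order_response <- ifelse(
      order_correct, design$probe_position,
      vapply(design$probe_position, function(p)
        sample(setdiff(1:3, p), 1L), numeric(1)))
    mu <- params$rt_meanlog + params$rt_replay_coef * replay_ms
    design$detail_rt <- stats::rlnorm(n, mu, params$rt_sdlog)
    design$order_rt <- stats::rlnorm(n, mu, params$rt_sdlog)
  })
  design$probe_replay_ms <- replay_ms
  design
}
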