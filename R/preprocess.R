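# Filtering, cropping, artifact rejection, baseline correction.
#
# Filters are Butterworth designs from the `signal` package, applied
# zero-phase (forward-backward) with odd-reflection edge padding. The IIR
# recursion is applied to all trial x channel traces at once (time loop,
# vectorized across traces) so that filtering full epoch sets stays fast.

filt_iir_matrix <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na_ <- length(a)
  n <- nrow(X)
  Y <- matrix(0, n, ncol(X))
  for (t in seq_len(n)) {
    acc <- b[1] * X[t, ]
    for (k in seq_len(min(nb, t) - 1L)) acc <- acc + b[k + 1L] * X[t - k, ]
    for (k in seq_len(min(na_, t) - 1L)) acc <- acc - a[k + 1L] * Y[t - k, ]
    Y[t, ] <- acc
  }
  Y
}

# Zero-phase filtering of the columns of X with odd-reflection padding.
zerophase_filter_matrix <- function(b, a, X) {
  npad <- 3L * (max(length(a), length(b)) - 1L)
  n <- nrow(X)
  if (n <= npad + 1L) stopf("epoch too short (%d samples) for this filter", n)
  top <- 2 * matrix(X[1, ], npad, ncol(X), byrow = TRUE) -
    X[seq(npad + 1L, 2L), , drop = FALSE]
  bot <- 2 * matrix(X[n, ], npad, ncol(X), byrow = TRUE) -
    X[seq(n - 1L, n - npad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- filt_iir_matrix(b, a, Xp)
  Y <- filt_iir_matrix(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y[seq(npad + 1L, npad + n), , drop = FALSE]
}

apply_filter_epochs <- function(epochs, b, a, label) {
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  Y <- zerophase_filter_matrix(b, a, X)
  epochs$data <- aperm(array(Y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  attr(epochs, "filters") <- c(attr(epochs, "filters"), list(label))
  epochs
}

#' Notch (band-stop) filter
#'
#' Removes mains interference with a zero-phase Butterworth band-stop of the
#' given order centered at `freq`, with `half_width` Hz on each side.
#'
#' @param epochs A [sensor_epochs] object.
#' @param freq Center frequency, Hz (default 50).
#' @param order Butterworth order (default 5).
#' @param half_width Half-width of the stop band, Hz (default 2).
#' @return Filtered epochs, dimensions unchanged.
#' @export
notch_filter <- function(epochs, freq = 50, order = 5, half_width = 2) {
  if (epochs$fs <= 2 * freq) stopf("fs (%g) must exceed twice the notch frequency", epochs$fs)
  bt <- signal::butter(order, c(freq - half_width, freq + half_width) / (epochs$fs / 2),
                       type = "stop")
  apply_filter_epochs(epochs, bt$b, bt$a,
                      list(kind = "notch", cutoff_hz = freq, order = order))
}

#' Low-pass filter
#'
#' Zero-phase Butterworth low-pass, used before event-related field averaging.
#'
#' @param epochs A [sensor_epochs] object.
#' @param cutoff Cutoff frequency, Hz (default 20).
#' @param order Butterworth order (default 5).
#' @return Filtered epochs, dimensions unchanged.
#' @export
lowpass_filter <- function(epochs, cutoff = 20, order = 5) {
  if (epochs$fs <= 2 * cutoff) stopf("fs (%g) must exceed twice the cutoff", epochs$fs)
  bt <- signal::butter(order, cutoff / (epochs$fs / 2), type = "low")
  apply_filter_epochs(epochs, bt$b, bt$a,
                      list(kind = "lowpass", cutoff_hz = cutoff, order = order))
}

#' Crop epochs to a time window
#'
#' Retains samples with `t_start <= t < t_end` (half-open, so abutting crops
#' never duplicate a sample). Metadata is preserved.
#'
#' @param epochs A [sensor_epochs] object.
#' @param t_start,t_end Window bounds in ms on the epoch time axis.
#' @return Cropped epochs.
#' @export
crop_epochs <- function(epochs, t_start, t_end) {
  if (t_start >= t_end) stopf("t_start must be below t_end")
  keep <- epochs$time_ms >= t_start - 1e-9 & epochs$time_ms < t_end - 1e-9
  if (!any(keep)) stopf("crop window [%g, %g) contains no samples", t_start, t_end)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$time_ms <- epochs$time_ms[keep]
  epochs
}

#' Reject epochs containing amplitude artifacts
#'
#' Removes every epoch whose absolute amplitude exceeds `threshold` (strictly)
#' in any channel at any sample, and reports what was removed. When the
#' rejected fraction exceeds `subject_flag_fraction` the report raises a
#' subject-level exclusion flag, mirroring participant exclusion for
#' artifact-laden recordings.
#'
#' @param epochs A [sensor_epochs] object.
#' @param threshold Amplitude threshold in tesla (default 1.5e-11).
#' @param subject_flag_fraction Rejected fraction above which the subject is
#'   flagged (default 0.3).
#' @return A list with `epochs` (clean) and `report` (fields `n_epochs_in`,
#'   `n_epochs_rejected`, `rejected_trial_ids`, `subject_flagged`,
#'   `filters_applied`).
#' @export
reject_artifact_epochs <- function(epochs, threshold = 1.5e-11,
                                   subject_flag_fraction = 0.3) {
  if (threshold <= 0) stopf("threshold must be positive")
  n <- n_trials(epochs)
  bad <- vapply(seq_len(n), function(i)
    max(abs(epochs$data[i, , ])) > threshold, logical(1))
  ids <- if (!is.null(epochs$trial_meta$trial_id)) {
    epochs$trial_meta$trial_id[bad]
  } else which(bad)
  report <- structure(list(
    n_epochs_in = n, n_epochs_rejected = sum(bad),
    rejected_trial_ids = ids,
    rejected_fraction = sum(bad) / n,
    subject_flagged = sum(bad) / n > subject_flag_fraction,
    threshold_tesla = threshold,
    filters_applied = attr(epochs, "filters") %||% list()
  ), class = "preprocessing_report")
  list(epochs = subset_trials(epochs, !bad), report = report)
}

#' @export
print.preprocessing_report <- function(x, ...) {
  cat(sprintf("<preprocessing_report> %d/%d epochs rejected (threshold %g T)%s\n",
              x$n_epochs_rejected, x$n_epochs_in, x$threshold_tesla,
              if (x$subject_flagged) " [SUBJECT FLAGGED]" else ""))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the whole epoch.
#'
#' @param epochs A [sensor_epochs] object.
#' @return Baseline-corrected epochs.
#' @export
baseline_correct <- function(epochs) {
  m <- rowMeans(epochs$data, dims = 2)  # trials x channels
  epochs$data <- epochs$data - as.vector(m)  # recycles over samples dimension
  epochs
}
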