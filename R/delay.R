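# Margin-thresholded state decoding of retention and ITI periods.

#' Define the retention and ITI analysis windows
#'
#' The retention window is 1000-4000 ms after the offset of the last encoded
#' stimulus (excluding its offset response); the control window is the
#' 3000 ms of intertrial interval before the first stimulus onset. Each is
#' partitioned into 20 ms bins (150 per window).
#'
#' @param retention_ms,iti_ms Window bounds, ms, relative to the respective
#'   alignment events.
#' @param width Bin width, ms.
#' @param fs Sampling rate, Hz.
#' @return A list with `retention` and `iti`, each a `time_bin_grid` plus
#'   `window_ms` and `n_bins`.
#' @export
define_analysis_windows <- function(retention_ms = c(1000, 4000),
                                    iti_ms = c(-3000, 0), width = 20, fs = 600) {
  mk <- function(w) {
    if (diff(w) < width) stopf("window [%g, %g) shorter than one bin", w[1], w[2])
    g <- make_time_bins(w[1], w[2], width, fs)
    g$window_ms <- w
    g$n_bins <- length(g$centers_ms)
    g
  }
  list(retention = mk(retention_ms), iti = mk(iti_ms))
}

# Combine three pairwise decision values into (label, d): the winning
# pairwise decision is the one with the largest absolute value (earliest
# classifier on exact ties, pairs ordered F-B, F-C, B-C); its sign picks the
# pair member, and d is the absolute value. A zero-margin winner falls to the
# pair's first category under the F < B < C order.
combine_pairwise <- function(scores, pairs = CATEGORY_PAIRS) {
  w <- max.col(abs(scores), ties.method = "first")
  n <- nrow(scores)
  d <- abs(scores[cbind(seq_len(n), w)])
  lab <- vapply(seq_len(n), function(i) {
    pr <- pairs[[w[i]]]
    if (scores[i, w[i]] >= 0) pr[1] else pr[2]
  }, character(1))
  list(label = lab, d = d)
}

#' Decode a single time bin
#'
#' Applies the three selected-bin pairwise classifiers to one bin's features
#' and combines their outputs: the class label is the category favored by the
#' pairwise decision of largest absolute value, and `d` is that absolute
#' decision distance.
#'
#' @param classifiers Named list of the three `pairwise_classifier` objects
#'   (from [train_bin_classifiers()]).
#' @param x Feature matrix (rows = bins/trials to decode) in the classifiers'
#'   feature space.
#' @return A data frame with `raw_label` and `d` (nonnegative).
#' @export
decode_bin <- function(classifiers, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  scores <- vapply(classifiers, decision_values, numeric(nrow(x)), x = x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  cb <- combine_pairwise(scores, lapply(classifiers, `[[`, "pair"))
  data.frame(raw_label = cb$label, d = cb$d, stringsAsFactors = FALSE)
}

#' Decode every bin of a delay-period window
#'
#' Slides the selected-bin classifiers over the 20 ms bins of the retention
#' or ITI window of each trial.
#'
#' @param classifiers Named list of three `pairwise_classifier` objects.
#' @param epochs Delay-period [sensor_epochs] covering the window.
#' @param window One element of [define_analysis_windows()].
#' @param period `"retention"` or `"iti"` (recorded in the output).
#' @return A `decoded_sequences` object: `labels` and `d` matrices
#'   (trials x bins), `bin_centers_ms`, `trial_id`, `period`.
#' @export
decode_period <- function(classifiers, epochs, window,
                          period = c("retention", "iti")) {
  period <- match.arg(period)
  n <- n_trials(epochs)
  labels <- matrix(NA_character_, n, window$n_bins)
  d <- matrix(NA_real_, n, window$n_bins)
  for (bi in seq_along(window$centers_ms)) {
    x <- extract_bin_features(epochs, window$centers_ms[bi], window)
    rec <- decode_bin(classifiers, x)
    labels[, bi] <- rec$raw_label
    d[, bi] <- rec$d
  }
  structure(list(labels = labels, d = d, bin_centers_ms = window$centers_ms,
                 trial_id = epochs$trial_meta$trial_id %||% seq_len(n),
                 period = period),
            class = "decoded_sequences")
}

#' Compute the d* rejection threshold
#'
#' Converts classifier reliability into a confidence threshold: if the
#' selected-bin classifiers are reliable a fraction `reliability` of the
#' time, the least-confident `1 - reliability` of retention-period decisions
#' are to be rejected. `d_star` is the lower empirical quantile (no
#' interpolation) of the retention decision distances at probability
#' `1 - reliability`, so that rejecting `d < d_star` removes exactly the
#' target fraction up to one rank position.
#'
#' @param d Numeric vector of retention-period decision distances (pooled
#'   across trials and bins for one subject).
#' @param reliability Fraction in (0, 1], typically the mean-over-pairs CV
#'   accuracy at the selected bin.
#' @return A `rejection_threshold`: `d_star`, `target_rejection_fraction`,
#'   `n`.
#' @export
compute_rejection_threshold <- function(d, reliability) {
  if (length(d) == 0L) stopf("no decision distances supplied")
  if (reliability <= 0 || reliability > 1) stopf("reliability must be in (0, 1]")
  s <- sort(d)
  # small epsilon keeps the rank exact when (1 - reliability) * n is an
  # integer up to floating-point error (e.g. 0.22 * 10000)
  k <- floor((1 - reliability) * length(d) + 1e-6)
  structure(list(d_star = s[k + 1L],
                 target_rejection_fraction = 1 - reliability,
                 n = length(d)),
            class = "rejection_threshold")
}

#' Apply the d* threshold to decoded sequences
#'
#' Relabels every bin whose decision distance falls below `d_star` as the
#' null state N; the same (retention-derived) threshold is applied to the
#' ITI control window.
#'
#' @param decoded A `decoded_sequences` object.
#' @param threshold A `rejection_threshold` from
#'   [compute_rejection_threshold()].
#' @return The `decoded_sequences` with sub-threshold labels set to `"N"`
#'   and a `rejected_fraction` field.
#' @export
apply_threshold <- function(decoded, threshold) {
  rej <- decoded$d < threshold$d_star
  decoded$labels[rej] <- "N"
  decoded$rejected_fraction <- mean(rej)
  decoded$d_star <- threshold$d_star
  decoded
}

#' @export
print.decoded_sequences <- function(x, ...) {
  cat(sprintf("<decoded_sequences> %s: %d trials x %d bins", x$period,
              nrow(x$labels), ncol(x$labels)))
  if (!is.null(x$rejected_fraction)) {
    cat(sprintf("; %.1f%% rejected as N (d* = %.3g)",
                100 * x$rejected_fraction, x$d_star))
  }
  cat("\n")
  invisible(x)
}
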