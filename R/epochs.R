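#' Epoched multichannel sensor data
#'
#' Container for epoched MEG sensor recordings: a trials x channels x samples
#' amplitude array (tesla) with its time axis, sampling rate, alignment event,
#' and per-trial metadata. All downstream operations (filtering, feature
#' extraction, decoding) consume and return this class.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param time_ms Numeric vector of per-sample times (ms) relative to the
#'   alignment event; strictly increasing with step `1000/fs`.
#' @param fs Sampling rate in Hz.
#' @param alignment One of `"stimulus_onset"`, `"last_stimulus_offset"`,
#'   `"first_stimulus_onset"`.
#' @param trial_meta Data frame of per-trial metadata, one row per epoch.
#' @param channel_ids Character vector of channel labels.
#' @return An object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, time_ms, fs,
                          alignment = c("stimulus_onset", "last_stimulus_offset",
                                        "first_stimulus_onset"),
                          trial_meta, channel_ids = NULL) {
  alignment <- match.arg(alignment)
  if (length(dim(data)) != 3L) stopf("`data` must be a 3-d array (trials x channels x samples)")
  if (is.null(channel_ids)) channel_ids <- sprintf("MEG%03d", seq_len(dim(data)[2]))
  x <- structure(list(
    data = data, time_ms = as.numeric(time_ms), fs = fs, alignment = alignment,
    trial_meta = trial_meta, channel_ids = channel_ids
  ), class = "sensor_epochs")
  validate_sensor_epochs(x)
  x
}

validate_sensor_epochs <- function(x) {
  d <- dim(x$data)
  if (length(x$time_ms) != d[3]) stopf("time axis length (%d) != samples dimension (%d)",
                                       length(x$time_ms), d[3])
  if (nrow(x$trial_meta) != d[1]) stopf("trial_meta rows (%d) != trials dimension (%d)",
                                        nrow(x$trial_meta), d[1])
  if (length(x$channel_ids) != d[2]) stopf("channel_ids length != channels dimension")
  dt <- diff(x$time_ms)
  if (any(dt <= 0)) stopf("time axis must be strictly increasing")
  if (max(abs(dt - 1000 / x$fs)) > 1e-6) stopf("time axis step inconsistent with fs")
  invisible(x)
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sensor_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms, aligned to %s\n",
              min(x$time_ms), max(x$time_ms), x$alignment))
  invisible(x)
}

#' @export
dim.sensor_epochs <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

# Subset epochs by trial index, keeping metadata aligned.
subset_trials <- function(x, idx) {
  x$data <- x$data[idx, , , drop = FALSE]
  x$trial_meta <- x$trial_meta[idx, , drop = FALSE]
  rownames(x$trial_meta) <- NULL
  x
}

EPOCHS_FORMAT_VERSION <- 1L

#' Save / load epochs to a self-describing directory container
#'
#' The container is a directory holding `header.json` (dimensions, sampling
#' rate, time axis, alignment, channel labels, format version), `trials.json`
#' (the per-trial metadata table), and `data.bin` (the amplitude array as
#' little-endian float64 in trials-fastest order, i.e. the R array layout).
#' A save/load round trip reproduces the array bit-exactly and the metadata
#' field-exactly.
#'
#' @param epochs A [sensor_epochs] object.
#' @param path Directory to write to (created if missing) / read from.
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns a
#'   [sensor_epochs] object.
#' @export
save_epochs <- function(epochs, path) {
  validate_sensor_epochs(epochs)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  header <- list(
    format = "megreplay-epochs", version = EPOCHS_FORMAT_VERSION,
    dims = d, fs = epochs$fs, alignment = epochs$alignment,
    # the time axis is uniform by construction; storing its origin and
    # reconstructing from fs keeps save/load round trips bit-exact
    time0_ms = epochs$time_ms[1], channel_ids = epochs$channel_ids
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(epochs$trial_meta, file.path(path, "trials.json"),
                       dataframe = "columns", digits = NA, na = "null")
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) stopf("not an epochs container: missing %s", hpath)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(header$format, "megreplay-epochs")) {
    stopf("unrecognized container format in header.json")
  }
  if (header$version > EPOCHS_FORMAT_VERSION) {
    stopf("unsupported epochs container version %s (this build reads <= %d)",
          header$version, EPOCHS_FORMAT_VERSION)
  }
  trial_meta <- jsonlite::read_json(file.path(path, "trials.json"),
                                    simplifyVector = TRUE)
  trial_meta <- as.data.frame(trial_meta, stringsAsFactors = FALSE)
  d <- as.integer(header$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(d), size = 8L, endian = "little")
  if (length(vals) != prod(d)) stopf("data.bin truncated: expected %d values, read %d",
                                     prod(d), length(vals))
  fs <- as.numeric(header$fs)
  time_ms <- as.numeric(header$time0_ms) + (seq_len(d[3]) - 1) * 1000 / fs
  sensor_epochs(array(vals, dim = d), time_ms, fs,
                header$alignment, trial_meta, header$channel_ids)
}
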