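#' Epoched EEG container
#'
#' Bundles a `[n_trials, n_channels, n_times]` voltage array (microvolts)
#' with its time grid, sampling frequency, per-trial metadata and sensor
#' layout. All analysis functions in the package consume and return this
#' container; operations are pure (no in-place mutation visible to callers).
#'
#' @param data Numeric array `[n_trials, n_channels, n_times]`, no NA.
#' @param times Numeric vector of sample times in ms, strictly increasing
#'   with uniform spacing `1000 / sfreq`.
#' @param sfreq Sampling frequency in Hz.
#' @param trials data.frame of per-trial metadata, one row per trial.
#'   Conventional columns: `participant`, `task`, `condition`, `block`,
#'   `item`, `report`, `rt_ms` (missing entries allowed).
#' @param layout A [make_scalp_layout()] `sensor_layout`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, trials, layout) {
  if (length(dim(data)) != 3) stop_schema("data must be a 3-d array")
  if (anyNA(data)) stop_schema("data must not contain NA")
  if (dim(data)[3] != length(times)) {
    stop_schema("length(times) must equal dim(data)[3]")
  }
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop_schema("times must be strictly increasing")
    if (max(abs(dt - 1000 / sfreq)) > 1e-6) {
      stop_schema("times spacing must equal 1000/sfreq ms")
    }
  }
  if (!is.data.frame(trials) || nrow(trials) != dim(data)[1]) {
    stop_schema("trials must be a data.frame with one row per trial")
  }
  if (!inherits(layout, "sensor_layout")) {
    stop_schema("layout must be a sensor_layout")
  }
  if (length(layout$channel_ids) != dim(data)[2]) {
    stop_schema("layout channel count must match dim(data)[2]")
  }
  structure(list(data = data, times = as.numeric(times),
                 sfreq = as.numeric(sfreq),
                 trials = as.data.frame(trials, stringsAsFactors = FALSE),
                 layout = layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d times (%.0f Hz, %g..%g ms)\n",
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  if (!is.null(x$trials$condition)) {
    tb <- table(x$trials$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset an epoch set by trial
#'
#' @param epochs An `epoch_set`.
#' @param idx Integer or logical index over trials.
#' @return A new `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$sfreq,
            epochs$trials[idx, , drop = FALSE], epochs$layout)
}

# index of samples with times inside [lo, hi] (inclusive endpoints)
time_index <- function(times, lo, hi) {
  which(times >= lo - 1e-9 & times <= hi + 1e-9)
}

#' Split an epoch set by participant
#'
#' @param epochs An `epoch_set` whose trial table has a `participant` column.
#' @return Named list of `epoch_set`, one per participant.
#' @export
split_by_participant <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  ids <- unique(epochs$trials$participant)
  out <- lapply(ids, function(p) subset_trials(epochs, epochs$trials$participant == p))
  names(out) <- as.character(ids)
  out
}
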