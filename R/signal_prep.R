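#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase windowed-sinc (Hamming) band-pass FIR per trial
#' and channel, as a single centred convolution so the net filter is
#' zero-phase. Edges are reflect-padded by half the kernel length. The
#' filter order targets a transition band of roughly half the low cutoff
#' (at least 2 Hz), capped so the kernel fits the epoch.
#'
#' @param epochs An `epoch_set`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < sfreq / 2`.
#' @return A filtered `epoch_set` of identical shape.
#' @export
bandpass_filter <- function(epochs, lo = 1, hi = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sfreq / 2
  if (!(lo > 0 && lo < hi)) stop_param("need 0 < lo < hi")
  if (hi >= nyq) stop_param("hi must be below the Nyquist frequency (",
                            nyq, " Hz)")
  trans <- max(min(lo * 0.5, 2), 1)
  ntaps <- ceiling(3.3 * epochs$sfreq / trans)
  nt <- dim(epochs$data)[3]
  ntaps <- min(ntaps, nt - 1)
  if (ntaps %% 2 == 1) ntaps <- ntaps - 1  # fir1 order -> odd-length kernel
  kern <- signal::fir1(ntaps, c(lo, hi) / nyq, type = "pass")
  half <- (length(kern) - 1) / 2
  out <- epochs$data
  d <- dim(out)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- out[i, j, ]
      xp <- c(rev(x[2:(half + 1)]), x, rev(x[(nt - half):(nt - 1)]))
      y <- stats::filter(xp, kern, method = "convolution", sides = 2)
      out[i, j, ] <- as.numeric(y[(half + 1):(half + nt)])
    }
  }
  epoch_set(out, epochs$times, epochs$sfreq, epochs$trials, epochs$layout)
}

#' Average samples into non-overlapping time bins
#'
#' Consecutive groups of `bin_ms / (1000 / sfreq)` samples are averaged;
#' output times are the centres (means) of each bin's member times and the
#' sampling frequency is updated accordingly. A trailing partial bin is
#' dropped.
#'
#' @param epochs An `epoch_set`.
#' @param bin_ms Bin width in ms; must be an integer multiple of the sample
#'   period.
#' @return A binned `epoch_set`.
#' @export
bin_time <- function(epochs, bin_ms) {
  stopifnot(inherits(epochs, "epoch_set"))
  period <- 1000 / epochs$sfreq
  k <- bin_ms / period
  if (abs(k - round(k)) > 1e-8 || round(k) < 1) {
    stop_param("bin_ms must be a positive integer multiple of the sample period (",
               signif(period, 6), " ms)")
  }
  k <- as.integer(round(k))
  if (k == 1) return(epochs)
  nt <- dim(epochs$data)[3]
  nbin <- nt %/% k
  idx <- seq_len(nbin * k)
  grp <- rep(seq_len(nbin), each = k)
  d <- dim(epochs$data)
  flat <- matrix(epochs$data[, , idx, drop = FALSE], nrow = d[1] * d[2])
  binned <- sapply(seq_len(nbin), function(b) {
    rowMeans(flat[, grp == b, drop = FALSE])
  })
  out <- array(binned, dim = c(d[1], d[2], nbin))
  new_times <- tapply(epochs$times[idx], grp, mean)
  epoch_set(out, as.numeric(new_times), epochs$sfreq / k, epochs$trials,
            epochs$layout)
}

#' Subtract a per-trial, per-channel baseline mean
#'
#' @param epochs An `epoch_set`.
#' @param window `(start_ms, end_ms)` baseline window (inclusive); must
#'   contain at least one sample.
#' @param mode Only `"subtract"` is implemented.
#' @return A baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0), mode = "subtract") {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode, "subtract")
  idx <- time_index(epochs$times, window[1], window[2])
  if (length(idx) == 0) stop_param("baseline window contains no samples")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- sweep(epochs$data, c(1, 2), base, "-")
  epoch_set(out, epochs$times, epochs$sfreq, epochs$trials, epochs$layout)
}

#' Morlet time-frequency transform with percent-change baseline
#'
#' Convolves each trial and channel with complex Morlet wavelets, takes
#' power, expresses it as percent change from the mean over
#' `baseline_window` (per trial, channel and frequency), and decimates the
#' time axis to `out_sfreq`.
#'
#' @param epochs An `epoch_set`.
#' @param freqs Wavelet centre frequencies in Hz (default integers 3..29,
#'   i.e. 27 wavelets spanning 3-30 Hz). All must be below Nyquist.
#' @param n_cycles Cycles per wavelet; default `pmax(freqs / 2, 3)`.
#' @param baseline_window Percent-change reference window, ms (default
#'   `c(-500, 0)`).
#' @param out_sfreq Output sampling rate in Hz after decimation (default
#'   50, i.e. 20-ms spacing). Must divide `sfreq` evenly.
#' @return An object of class `tfr_epoch_set`: list with `data`
#'   `[n_trials, n_channels, n_freqs, n_times]` (percent change), `freqs`,
#'   `times`, `sfreq`, `baseline_window`, `trials`, `layout`.
#' @export
morlet_tfr <- function(epochs, freqs = 3:29, n_cycles = NULL,
                       baseline_window = c(-500, 0), out_sfreq = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (max(freqs) >= epochs$sfreq / 2) {
    stop_param("max(freqs) must be below the Nyquist frequency")
  }
  n_cycles <- n_cycles %||% pmax(freqs / 2, 3)
  if (length(n_cycles) == 1) n_cycles <- rep(n_cycles, length(freqs))
  dec <- epochs$sfreq / out_sfreq
  if (abs(dec - round(dec)) > 1e-8 || dec < 1) {
    stop_param("out_sfreq must divide sfreq evenly")
  }
  dec <- as.integer(round(dec))
  nt <- dim(epochs$data)[3]
  d <- dim(epochs$data)
  dt <- 1 / epochs$sfreq
  # frequency-domain wavelets for overlap-free full convolution via FFT
  nfft <- stats::nextn(2 * nt, 2)
  wav_f <- lapply(seq_along(freqs), function(k) {
    f <- freqs[k]
    sigma_t <- n_cycles[k] / (2 * pi * f)
    half <- ceiling(5 * sigma_t / dt)
    tt <- seq(-half, half) * dt
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))  # unit-energy normalisation
    list(fft = stats::fft(c(w, complex(real = rep(0, nfft - length(w))))),
         half = half)
  })
  keep <- seq(1, nt, by = dec)
  # baseline taken on the output grid so corrected data average to exactly
  # zero over the baseline window of the returned object
  bidx <- time_index(epochs$times[keep], baseline_window[1], baseline_window[2])
  if (length(bidx) == 0) stop_param("baseline window contains no samples")
  out <- array(0, dim = c(d[1], d[2], length(freqs), length(keep)))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      xf <- stats::fft(c(epochs$data[i, j, ], rep(0, nfft - nt)))
      for (k in seq_along(freqs)) {
        conv <- stats::fft(xf * wav_f[[k]]$fft, inverse = TRUE) / nfft
        h <- wav_f[[k]]$half
        pw <- (Mod(conv[(h + 1):(h + nt)])^2)[keep]
        mb <- mean(pw[bidx])
        if (mb <= 0) {
          stop(errorCondition("baseline power is not positive; cannot form percent change",
                              class = c("intrudetect_numeric_error",
                                        "intrudetect_error")))
        }
        out[i, j, k, ] <- 100 * (pw - mb) / mb
      }
    }
  }
  structure(list(data = out, freqs = freqs, times = epochs$times[keep],
                 sfreq = out_sfreq, baseline_window = baseline_window,
                 trials = epochs$trials, layout = epochs$layout),
            class = "tfr_epoch_set")
}

#' @export
print.tfr_epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tfr_epoch_set> %d trials x %d channels x %d freqs x %d times (%.0f Hz)\n",
              d[1], d[2], d[3], d[4], x$sfreq))
  invisible(x)
}
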