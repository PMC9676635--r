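#' Configuration for the simulated attention task
#'
#' The attention task the simulator emulates presents a central image at
#' time 0; on "intrusion" trials an unexpected background image appears
#' `background_image_onset_ms` later and captures attention reflexively,
#' evoking a transient occipital theta-band component. "Exploration" trials
#' carry a component with a different latency and topography (a background
#' image that is inspected voluntarily), and "non_intrusion" trials are
#' noise only.
#'
#' @param n_trials_per_condition Trials per condition (default 30).
#' @param n_channels Montage size (default 32).
#' @param sfreq Sampling frequency, Hz (>= 100; default 100).
#' @param epoch_window `(start_ms, end_ms)`; must span at least
#'   `[-250, 1500]` ms (default exactly that).
#' @param background_image_onset_ms Onset of the background image relative
#'   to the central image, ms (default 200).
#' @param intrusion_component Named list `latency_ms` (after background
#'   onset; default 110, the latency of maximal attentional-capture
#'   decoding), `width_ms` (Gaussian envelope FWHM, default 200),
#'   `carrier_hz` (default 5, theta), `amplitude` (microvolts, default 5),
#'   `center`/`width` of the scalp weight map (occipital by default).
#' @param exploration_component Same structure; default latency 160 ms,
#'   10 Hz carrier, right-parietal topography.
#' @param noise Named list `ar_coefficient` (AR(1) coefficient in `[0, 1)`,
#'   default 0.9), `std` (marginal noise sd, microvolts, default 5),
#'   `alpha_band_amplitude` (shared 10 Hz background oscillation with random
#'   phase per trial, default 2).
#' @param seed Integer seed.
#' @return A validated list of class `attention_sim_config`.
#' @export
attention_sim_config <- function(n_trials_per_condition = 30,
                                 n_channels = 32,
                                 sfreq = 100,
                                 epoch_window = c(-250, 1500),
                                 background_image_onset_ms = 200,
                                 intrusion_component = list(),
                                 exploration_component = list(),
                                 noise = list(),
                                 seed = 1L) {
  ic <- utils::modifyList(list(latency_ms = 110, width_ms = 200,
                               carrier_hz = 5, amplitude = 5,
                               center = c(0, -0.8), width = 0.35),
                          intrusion_component)
  ec <- utils::modifyList(list(latency_ms = 160, width_ms = 200,
                               carrier_hz = 10, amplitude = 5,
                               center = c(0.55, -0.1), width = 0.35),
                          exploration_component)
  nz <- utils::modifyList(list(ar_coefficient = 0.9, std = 5,
                               alpha_band_amplitude = 2),
                          noise)
  if (sfreq < 100) stop_config("sfreq must be >= 100 Hz")
  if (epoch_window[1] > -250 || epoch_window[2] < 1500) {
    stop_config("epoch_window must span at least [-250, 1500] ms")
  }
  if (ic$amplitude < 0 || ec$amplitude < 0) stop_config("amplitudes must be >= 0")
  if (nz$ar_coefficient < 0 || nz$ar_coefficient >= 1) {
    stop_config("ar_coefficient must be in [0, 1)")
  }
  if (n_trials_per_condition < 1) stop_config("n_trials_per_condition must be >= 1")
  structure(list(n_trials_per_condition = as.integer(n_trials_per_condition),
                 n_channels = as.integer(n_channels), sfreq = sfreq,
                 epoch_window = epoch_window,
                 background_image_onset_ms = background_image_onset_ms,
                 intrusion_component = ic, exploration_component = ec,
                 noise = nz, seed = as.integer(seed)),
            class = "attention_sim_config")
}

# Gaussian-windowed sinusoid, phase-locked to its centre: the evoked
# transient planted for intrusion/exploration components and TNT events.
component_waveform <- function(times, t0, width_ms, carrier_hz, amplitude) {
  sigma <- width_ms / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(times - t0)^2 / (2 * sigma^2)) *
    cos(2 * pi * carrier_hz * (times - t0) / 1000)
}

# AR(1) channel noise plus a shared alpha oscillation with random phase per
# trial, weighted toward occipital sensors. Fills one trial's [ch x time]
# matrix; assumes the caller set the RNG state.
noise_trial <- function(n_channels, times, sfreq, nz, alpha_weights) {
  nt <- length(times)
  innov_sd <- nz$std * sqrt(1 - nz$ar_coefficient^2)
  e <- matrix(stats::rnorm(n_channels * nt, sd = innov_sd), n_channels, nt)
  x <- t(apply(e, 1, function(row) {
    as.numeric(stats::filter(row, nz$ar_coefficient, method = "recursive"))
  }))
  phase <- stats::runif(1, 0, 2 * pi)
  alpha <- nz$alpha_band_amplitude * sin(2 * pi * 10 * times / 1000 + phase)
  x + outer(alpha_weights, alpha)
}

#' Simulate an attention-task epoch set with planted components
#'
#' Generates `3 * n_trials_per_condition` epochs: intrusion trials carry a
#' Gaussian-windowed sinusoid at `background_image_onset_ms +
#' intrusion_component$latency_ms`, projected onto an occipital weight map;
#' exploration trials carry the exploration component; non-intrusion trials
#' are noise only. Noise is AR(1) per channel plus a shared alpha
#' oscillation with random phase per trial.
#'
#' @param cfg An [attention_sim_config()].
#' @param layout A [make_scalp_layout()] with `cfg$n_channels` channels.
#' @param participant Participant id stored in the trial table (default 1).
#' @return List with `epochs` (an `epoch_set`) and `truth` (data.frame with
#'   per-trial condition, planted component latency in ms on the epoch time
#'   axis (central image at 0, so the default intrusion component lands at
#'   310 ms), and amplitude; `NA` latency for noise-only trials).
#' @export
simulate_attention_dataset <- function(cfg, layout, participant = 1L) {
  stopifnot(inherits(cfg, "attention_sim_config"))
  if (length(layout$channel_ids) != cfg$n_channels) {
    stop_config("layout channel count must match cfg$n_channels")
  }
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2], by = 1000 / cfg$sfreq)
  for (comp in list(cfg$intrusion_component, cfg$exploration_component)) {
    t0 <- cfg$background_image_onset_ms + comp$latency_ms
    if (t0 < times[1] || t0 > times[length(times)]) {
      stop_config("component latency falls outside the epoch window")
    }
  }
  n_per <- cfg$n_trials_per_condition
  conds <- rep(c("intrusion", "non_intrusion", "exploration"), each = n_per)
  n_trials <- length(conds)
  w_int <- spatial_pattern(layout, cfg$intrusion_component$center,
                           cfg$intrusion_component$width)
  w_exp <- spatial_pattern(layout, cfg$exploration_component$center,
                           cfg$exploration_component$width)
  w_alpha <- 0.5 + 0.5 * spatial_pattern(layout, c(0, -0.8), 0.6)
  dat <- array(0, dim = c(n_trials, cfg$n_channels, length(times)))
  lat <- rep(NA_real_, n_trials)
  amp <- rep(0, n_trials)
  with_seed(child_seed(cfg$seed, 11L, participant), {
    for (i in seq_len(n_trials)) {
      tr <- noise_trial(cfg$n_channels, times, cfg$sfreq, cfg$noise, w_alpha)
      comp <- switch(conds[i], intrusion = cfg$intrusion_component,
                     exploration = cfg$exploration_component, NULL)
      if (!is.null(comp)) {
        t0 <- cfg$background_image_onset_ms + comp$latency_ms
        wav <- component_waveform(times, t0, comp$width_ms, comp$carrier_hz,
                                  comp$amplitude)
        w <- if (conds[i] == "intrusion") w_int else w_exp
        tr <- tr + outer(w, wav)
        lat[i] <- t0
        amp[i] <- comp$amplitude
      }
      dat[i, , ] <- tr
    }
  })
  trials <- data.frame(participant = as.integer(participant),
                       task = "attention", condition = conds,
                       block = NA_integer_, item = NA_integer_,
                       report = NA_integer_, rt_ms = NA_real_,
                       stringsAsFactors = FALSE)
  truth <- data.frame(trial = seq_len(n_trials), condition = conds,
                      latency_ms = lat, amplitude = amp,
                      stringsAsFactors = FALSE)
  list(epochs = epoch_set(dat, times, cfg$sfreq, trials, layout),
       truth = truth)
}
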