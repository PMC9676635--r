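#' Configuration for the simulated Think/No-Think task
#'
#' Emulates the No-Think arm of a TNT experiment: each participant sees
#' `n_items_nothink` suppression cues once per block over `n_blocks` blocks
#' and reports after each trial whether the associated memory intruded.
#' The per-block intrusion probability declines linearly with a
#' participant-specific slope (plus block-level jitter), reported intrusive
#' trials receive transient planted EEG events sharing the attention task's
#' intrusion topography and carrier, and each participant's
#' suppression-induced forgetting (SIF) is coupled to their intrusion slope.
#'
#' @param n_participants Number of participants (default 24).
#' @param n_items_nothink No-Think items per participant (default 24).
#' @param n_blocks Suppression blocks (default 8).
#' @param epoch_window TNT epoch window in ms (default `c(-200, 3000)`).
#' @param event_latency_range_ms Uniform range for planted event latencies,
#'   ms after cue onset (default `c(400, 800)`, centred on the ~600 ms
#'   intrusive-reactivation peak). Must lie inside the epoch and after 0.
#' @param events_per_intrusive_trial Planted events per reported-intrusive
#'   trial (default 1).
#' @param event_amplitude Event amplitude in microvolts (default 5).
#' @param intrusion_decay Named list: `start` (block-1 intrusion
#'   probability, default 0.8), `slope_mean` and `slope_sd` (per-block
#'   change, defaults -0.1 and 0.05), `block_sd` (block-level jitter of the
#'   true probability, default 0.15; this jitter is part of the recorded
#'   truth, and its size keeps the item-sampling noise small relative to
#'   the true blockwise variation so planted slopes are recoverable at the
#'   24-item design). Probabilities are clipped to [0, 1].
#' @param sif_coupling Target correlation between the per-participant true
#'   intrusion slope (Pearson r of true probability against block) and true
#'   SIF; in `[-1, 1]` (default -0.5).
#' @param recall_model Named list: `baseline_rate` (default 0.85),
#'   `nothink_penalty` (mean SIF in probability units, default 0.10),
#'   `sif_sd` (between-participant sd of true SIF, default 0.15),
#'   `think_boost` (default 0.05).
#' @param seed Integer seed.
#' @return A validated list of class `tnt_sim_config`.
#' @export
tnt_sim_config <- function(n_participants = 24,
                           n_items_nothink = 24,
                           n_blocks = 8,
                           epoch_window = c(-200, 3000),
                           event_latency_range_ms = c(400, 800),
                           events_per_intrusive_trial = 1,
                           event_amplitude = 5,
                           intrusion_decay = list(),
                           sif_coupling = -0.5,
                           recall_model = list(),
                           seed = 1L) {
  dec <- utils::modifyList(list(start = 0.8, slope_mean = -0.1,
                                slope_sd = 0.05, block_sd = 0.15),
                           intrusion_decay)
  rec <- utils::modifyList(list(baseline_rate = 0.85, nothink_penalty = 0.10,
                                sif_sd = 0.15, think_boost = 0.05),
                           recall_model)
  if (event_latency_range_ms[1] <= 0 ||
      event_latency_range_ms[1] < epoch_window[1] ||
      event_latency_range_ms[2] > epoch_window[2] ||
      event_latency_range_ms[1] > event_latency_range_ms[2]) {
    stop_config("event_latency_range_ms must lie within the epoch window and after 0 ms")
  }
  if (abs(sif_coupling) > 1) stop_config("sif_coupling must be in [-1, 1]")
  if (event_amplitude < 0) stop_config("event_amplitude must be >= 0")
  if (n_blocks < 2) stop_config("n_blocks must be >= 2")
  structure(list(n_participants = as.integer(n_participants),
                 n_items_nothink = as.integer(n_items_nothink),
                 n_blocks = as.integer(n_blocks),
                 epoch_window = epoch_window,
                 event_latency_range_ms = event_latency_range_ms,
                 events_per_intrusive_trial = as.integer(events_per_intrusive_trial),
                 event_amplitude = event_amplitude,
                 intrusion_decay = dec, sif_coupling = sif_coupling,
                 recall_model = rec, seed = as.integer(seed)),
            class = "tnt_sim_config")
}

#' Simulate TNT behavioral ground truth (no EEG)
#'
#' Draws, for every participant, the true blockwise intrusion probabilities,
#' the binary intrusion report of every item x block trial, the true
#' intrusion slope (Pearson r of true probability against block index) and
#' the true SIF, coupled to the slope with correlation `sif_coupling`.
#' [simulate_tnt_dataset()] uses this and then plants EEG events on the
#' reported-intrusive trials, so behavioral and neural ground truth can be
#' decoupled (e.g. EEG amplitude 0 for null tests).
#'
#' @param cfg A [tnt_sim_config()].
#' @return List of class `tnt_behavior_truth`: `prob` (participant, item,
#'   block, `p_true`, `report` in {0,1}, `report_raw` on the 1-3 scale),
#'   `participants` (participant, `slope_true`, `sif_true`).
#' @export
simulate_tnt_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "tnt_sim_config"))
  np <- cfg$n_participants; ni <- cfg$n_items_nothink; nb <- cfg$n_blocks
  dec <- cfg$intrusion_decay
  blocks <- seq_len(nb)
  out <- with_seed(child_seed(cfg$seed, 23L), {
    slope_lin <- stats::rnorm(np, dec$slope_mean, dec$slope_sd)
    p_true <- matrix(0, np, nb)
    for (p in seq_len(np)) {
      p_true[p, ] <- pmin(pmax(dec$start + slope_lin[p] * (blocks - 1) +
                                 stats::rnorm(nb, 0, dec$block_sd), 0), 1)
    }
    slope_true <- apply(p_true, 1, function(pr) {
      if (stats::sd(pr) < 1e-12) 0 else stats::cor(pr, blocks)
    })
    # true SIF coupled to the realized slope with correlation sif_coupling
    z <- if (np > 1 && stats::sd(slope_true) > 0) {
      as.numeric(scale(slope_true))
    } else rep(0, np)
    rho <- cfg$sif_coupling
    e <- stats::rnorm(np)
    sif_true <- cfg$recall_model$nothink_penalty +
      cfg$recall_model$sif_sd * (rho * z + sqrt(1 - rho^2) * e)
    grid <- expand.grid(block = seq_len(nb), item = seq_len(ni),
                        participant = seq_len(np))
    grid <- grid[, c("participant", "item", "block")]
    grid$p_true <- p_true[cbind(grid$participant, grid$block)]
    grid$report <- stats::rbinom(nrow(grid), 1, grid$p_true)
    # raw 1-3 scale: 1 = no intrusion, 2/3 = brief/vivid intrusion
    grid$report_raw <- ifelse(grid$report == 1,
                              2L + stats::rbinom(nrow(grid), 1, 0.5), 1L)
    list(prob = grid,
         participants = data.frame(participant = seq_len(np),
                                   slope_true = slope_true,
                                   sif_true = sif_true))
  })
  structure(out, class = "tnt_behavior_truth")
}

#' Simulate a TNT epoch set with planted intrusion events
#'
#' For every reported-intrusive No-Think trial, plants
#' `events_per_intrusive_trial` transient events (Gaussian-windowed
#' sinusoids with the attention task's intrusion carrier, envelope and
#' occipital topography, scaled by `event_amplitude`) at latencies drawn
#' uniformly from `event_latency_range_ms`. Non-intrusive trials are noise
#' only. Trials are ordered participant, block, item.
#'
#' @param cfg A [tnt_sim_config()].
#' @param layout Sensor layout shared with the attention task.
#' @param attention_cfg The [attention_sim_config()] supplying the intrusion
#'   component's topography, carrier and envelope, and the noise model.
#' @param behavior Optional precomputed [simulate_tnt_behavior()] truth; by
#'   default it is generated from `cfg`.
#' @return List with `epochs` (an `epoch_set`; trial table columns
#'   `participant`, `task = "tnt"`, `condition = "no_think"`, `block`,
#'   `item`, `report` in {0,1}) and `truth` (class `generation_truth`: the
#'   behavioral truth plus `events`, a data.frame of planted event latencies
#'   and amplitudes per trial).
#' @export
simulate_tnt_dataset <- function(cfg, layout, attention_cfg, behavior = NULL) {
  stopifnot(inherits(cfg, "tnt_sim_config"),
            inherits(attention_cfg, "attention_sim_config"))
  if (length(layout$channel_ids) != attention_cfg$n_channels) {
    stop_config("layout channel count must match attention_cfg$n_channels")
  }
  beh <- behavior %||% simulate_tnt_behavior(cfg)
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2],
               by = 1000 / attention_cfg$sfreq)
  grid <- beh$prob[order(beh$prob$participant, beh$prob$block, beh$prob$item), ]
  n_trials <- nrow(grid)
  nch <- attention_cfg$n_channels
  comp <- attention_cfg$intrusion_component
  w_int <- spatial_pattern(layout, comp$center, comp$width)
  w_alpha <- 0.5 + 0.5 * spatial_pattern(layout, c(0, -0.8), 0.6)
  dat <- array(0, dim = c(n_trials, nch, length(times)))
  ev_list <- vector("list", n_trials)
  with_seed(child_seed(cfg$seed, 37L), {
    for (i in seq_len(n_trials)) {
      tr <- noise_trial(nch, times, attention_cfg$sfreq, attention_cfg$noise,
                        w_alpha)
      if (grid$report[i] == 1) {
        lat <- stats::runif(cfg$events_per_intrusive_trial,
                            cfg$event_latency_range_ms[1],
                            cfg$event_latency_range_ms[2])
        for (t0 in lat) {
          wav <- component_waveform(times, t0, comp$width_ms, comp$carrier_hz,
                                    cfg$event_amplitude)
          tr <- tr + outer(w_int, wav)
        }
        ev_list[[i]] <- data.frame(trial = i,
                                   participant = grid$participant[i],
                                   item = grid$item[i], block = grid$block[i],
                                   latency_ms = lat,
                                   amplitude = cfg$event_amplitude)
      }
      dat[i, , ] <- tr
    }
  })
  events <- if (any(!vapply(ev_list, is.null, logical(1)))) {
    do.call(rbind, ev_list)
  } else {
    data.frame(trial = integer(), participant = integer(), item = integer(),
               block = integer(), latency_ms = numeric(), amplitude = numeric())
  }
  trials <- data.frame(participant = grid$participant, task = "tnt",
                       condition = "no_think", block = grid$block,
                       item = grid$item, report = grid$report,
                       rt_ms = NA_real_, stringsAsFactors = FALSE)
  truth <- structure(list(prob = grid, participants = beh$participants,
                          events = events),
                     class = "generation_truth")
  list(epochs = epoch_set(dat, times, attention_cfg$sfreq, trials, layout),
       truth = truth)
}

#' Simulate the final recall table
#'
#' Draws per-item recall for Think, No-Think and Baseline conditions.
#' Baseline items are recalled at `recall_model$baseline_rate`, Think items
#' at rate `baseline_rate + think_boost`, and each participant's No-Think
#' items at `baseline_rate - sif_true` (clipped to [0.02, 0.98]), so that
#' the expected SIF equals the true SIF planted by
#' [simulate_tnt_behavior()].
#'
#' @param cfg A [tnt_sim_config()].
#' @param truth A `generation_truth` or `tnt_behavior_truth` with a
#'   `participants` component.
#' @return data.frame (participant, item, condition, recalled) — one row per
#'   participant x item x condition, `n_items_nothink` items per condition.
#' @export
simulate_recall_table <- function(cfg, truth) {
  stopifnot(inherits(cfg, "tnt_sim_config"))
  pt <- truth$participants
  ni <- cfg$n_items_nothink
  rec <- cfg$recall_model
  with_seed(child_seed(cfg$seed, 53L), {
    rows <- lapply(seq_len(nrow(pt)), function(j) {
      p <- pt$participant[j]
      p_nt <- pmin(pmax(rec$baseline_rate - pt$sif_true[j], 0.02), 0.98)
      p_th <- pmin(rec$baseline_rate + rec$think_boost, 0.98)
      data.frame(participant = p,
                 item = rep(seq_len(ni), 3),
                 condition = rep(c("Think", "NoThink", "Baseline"), each = ni),
                 recalled = c(stats::rbinom(ni, 1, p_th),
                              stats::rbinom(ni, 1, p_nt),
                              stats::rbinom(ni, 1, rec$baseline_rate)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
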