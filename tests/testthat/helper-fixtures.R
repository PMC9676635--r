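# Shared fixtures and independent oracles, all built in code at test time.

# minimal epoch_set wrapping one time series replicated over channels
series_epochs <- function(x, sfreq, n_channels = 4, t0 = 0,
                          condition = "a", layout = NULL) {
  nt <- length(x)
  layout <- layout %||% make_scalp_layout(n_channels, seed = 0)
  arr <- aperm(array(x, dim = c(nt, n_channels, 1)), c(3, 2, 1))
  epoch_set(arr, seq(t0, by = 1000 / sfreq, length.out = nt), sfreq,
            data.frame(participant = 1L, task = "t", condition = condition,
                       block = NA_integer_, item = NA_integer_,
                       report = NA_integer_, rt_ms = NA_real_),
            layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small but decodable attention config; amplitude 12 is the high-SNR regime
small_attention_cfg <- function(amplitude = 12, n_trials = 24, seed = 1L) {
  attention_sim_config(n_trials_per_condition = n_trials, n_channels = 12,
                       intrusion_component = list(amplitude = amplitude),
                       exploration_component = list(amplitude = amplitude),
                       seed = seed)
}

small_tnt_cfg <- function(n_participants = 1, n_items = 12,
                          event_amplitude = 12, seed = 1L, ...) {
  tnt_sim_config(n_participants = n_participants, n_items_nothink = n_items,
                 event_amplitude = event_amplitude, seed = seed, ...)
}

# classifier settings used by most decoding tests (trees reduced where the
# property under test does not depend on forest size)
fast_spec <- function(n_estimators = 50, seed = 1L) {
  classifier_spec(n_estimators = n_estimators, seed = seed)
}

# reduced-resolution cohort used by the end-to-end checks: 40-ms bins keep
# the grids small while leaving the 200-ms-wide planted events resolvable
binned_cohort <- function(seed, n_participants = 8, n_items = 12,
                          amplitude = 12, bin_ms = 40,
                          event_amplitude = amplitude, ...) {
  coh <- simulate_cohort(small_attention_cfg(amplitude = amplitude),
                         small_tnt_cfg(n_participants = n_participants,
                                       n_items = n_items,
                                       event_amplitude = event_amplitude,
                                       ...),
                         seed = seed)
  coh$attention <- lapply(coh$attention, bin_time, bin_ms = bin_ms)
  coh$tnt <- lapply(coh$tnt, bin_time, bin_ms = bin_ms)
  coh
}

# O(n1 * n0) pairwise-counting AUC oracle
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive sign-flip oracle for the one-sample cluster permutation test:
# enumerates all 2^n sign patterns and returns the exact p of the largest
# observed cluster mass (by |mass|), using the same clustering rule.
exhaustive_cluster_p <- function(data, mu0 = 0, alpha_form = 0.05,
                                 tail = "two_sided") {
  X <- as.matrix(data) - mu0
  n <- nrow(X)
  tcrit <- if (tail == "two_sided") {
    stats::qt(1 - alpha_form / 2, n - 1)
  } else {
    stats::qt(1 - alpha_form, n - 1)
  }
  tstat <- function(M) {
    m <- colMeans(M)
    s <- apply(M, 2, stats::sd)
    tt <- m / (s / sqrt(n))
    tt[!is.finite(tt)] <- sign(m[!is.finite(tt)]) * 1e12
    tt
  }
  max_mass <- function(tv) {
    best <- 0
    run <- 0
    for (v in tv) {
      if (v > tcrit) run <- run + v else {
        best <- max(best, abs(run)); run <- 0
      }
    }
    best <- max(best, abs(run))
    if (tail == "two_sided") {
      run <- 0
      for (v in tv) {
        if (v < -tcrit) run <- run + v else {
          best <- max(best, abs(run)); run <- 0
        }
      }
      best <- max(best, abs(run))
    }
    best
  }
  obs <- max_mass(tstat(X))
  if (obs == 0) return(1)
  count <- 0L
  for (bits in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(bits, 2^(0:(n - 1))) > 0, -1, 1)
    if (max_mass(tstat(X * s)) >= obs - 1e-12) count <- count + 1L
  }
  count / 2^n
}
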