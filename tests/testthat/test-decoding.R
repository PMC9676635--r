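make_attention_binned <- function(amplitude = 12, seed = 1, bin_ms = 40) {
  cfg <- small_attention_cfg(amplitude = amplitude, seed = seed)
  lay <- make_scalp_layout(cfg$n_channels, seed = 2)
  bin_time(simulate_attention_dataset(cfg, lay)$epochs, bin_ms)
}

test_that("per-timepoint decoding finds the planted attentional component", {
  ep <- make_attention_binned(seed = 31)
  dr <- cv_auc_timecourse(ep, "intrusion", "non_intrusion",
                          fast_spec(seed = 4), n_folds = 8)
  expect_true(all(dr$auc_mean >= 0 & dr$auc_mean <= 1))
  expect_equal(dr$auc_mean, colMeans(dr$auc_per_fold))
  in_win <- dr$times >= 210 & dr$times <= 450
  expect_gt(max(dr$auc_mean[in_win]), 0.7)
  expect_gt(mean(dr$auc_mean[in_win]) - mean(dr$auc_mean[!in_win]), 0.05)
  # fixed seed => fixed folds => identical result on rerun
  dr2 <- cv_auc_timecourse(ep, "intrusion", "non_intrusion",
                           fast_spec(seed = 4), n_folds = 8)
  expect_identical(dr$auc_per_fold, dr2$auc_per_fold)
})

test_that("decoding errors usefully when folds outnumber class trials", {
  ep <- make_attention_binned(seed = 31)
  keep <- c(which(ep$trials$condition == "intrusion")[1:5],
            which(ep$trials$condition == "non_intrusion"))
  expect_error(cv_auc_timecourse(subset_trials(ep, keep), "intrusion",
                                 "non_intrusion", fast_spec(), n_folds = 8),
               class = "intrudetect_fold_error")
})

test_that("time-frequency decoding peaks in theta for a 5 Hz planted carrier", {
  cfg <- small_attention_cfg(amplitude = 14, n_trials = 20, seed = 41)
  lay <- make_scalp_layout(cfg$n_channels, seed = 2)
  ep <- simulate_attention_dataset(cfg, lay)$epochs
  tfr <- morlet_tfr(ep, freqs = c(3, 5, 7, 10, 14, 20),
                    baseline_window = c(-250, 0), out_sfreq = 25)
  td <- cv_auc_timefreq(tfr, "intrusion", "non_intrusion",
                        fast_spec(n_estimators = 30, seed = 6), n_folds = 4)
  expect_true(all(td$auc >= 0 & td$auc <= 1))
  lat_idx <- which.min(abs(td$times - 310))
  win <- max(1, lat_idx - 2):min(length(td$times), lat_idx + 2)
  peak_freq <- td$freqs[which.max(apply(td$auc[, win, drop = FALSE], 1, max))]
  expect_lte(peak_freq, 7)  # theta band
})

test_that("a single-frequency TFR reduces decoding to the timecourse path", {
  cfg <- small_attention_cfg(amplitude = 12, n_trials = 12, seed = 51)
  lay <- make_scalp_layout(cfg$n_channels, seed = 2)
  ep <- simulate_attention_dataset(cfg, lay)$epochs
  tfr <- morlet_tfr(ep, freqs = 5, baseline_window = c(-250, 0),
                    out_sfreq = 25)
  spec <- fast_spec(n_estimators = 20, seed = 8)
  td <- cv_auc_timefreq(tfr, "intrusion", "non_intrusion", spec, n_folds = 4)
  # rebuild the single-frequency power series as a voltage epoch set
  pow <- epoch_set(tfr$data[, , 1, ], tfr$times, tfr$sfreq, tfr$trials,
                   tfr$layout)
  dr <- cv_auc_timecourse(pow, "intrusion", "non_intrusion", spec,
                          n_folds = 4)
  expect_equal(as.numeric(td$auc[1, ]), dr$auc_mean, tolerance = 1e-12)
})

test_that("sensor contrast localizes the planted occipital pattern", {
  cfg <- small_attention_cfg(amplitude = 14, n_trials = 30, seed = 61)
  lay <- make_scalp_layout(cfg$n_channels, seed = 2)
  ep <- simulate_attention_dataset(cfg, lay)$epochs
  sc <- sensor_contrast(ep, "intrusion", "non_intrusion", window = c(280, 340),
                        n_perm = 500, seed = 3)
  pos_sig <- sc$significant[sc$t[sc$significant] > 0]
  expect_gt(length(pos_sig), 0)
  occ <- lay$channel_ids[lay$region_tags == "occipital"]
  expect_true(all(pos_sig %in% occ))

  # identical conditions: relabel half the non-intrusion trials
  noni <- subset_trials(ep, ep$trials$condition == "non_intrusion")
  noni$trials$condition[seq(1, nrow(noni$trials), by = 2)] <- "fake"
  sc0 <- sensor_contrast(noni, "fake", "non_intrusion", window = c(280, 340),
                         n_perm = 500, seed = 3)
  expect_length(sc0$significant, 0)
  expect_warning(sensor_contrast(ep, "intrusion", "non_intrusion",
                                 n_perm = 50, seed = 1), "coarse")
})
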