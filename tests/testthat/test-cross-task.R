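# shared high-SNR single-participant fixture at 10-ms resolution
xt_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_attention_cfg(amplitude = 12, n_trials = 16, seed = 71)
      lay <- make_scalp_layout(cfg$n_channels, seed = 2)
      att <- simulate_attention_dataset(cfg, lay)$epochs
      cache <<- list(cfg = cfg, lay = lay, att = att)
    }
    cache
  }
})

test_that("bank training covers the inclusive window at the native 10-ms grid", {
  fx <- xt_fixture()
  spec <- fast_spec(n_estimators = 10, seed = 1)
  bank <- train_bank(fx$att, window = c(250, 500), spec = spec)
  expect_length(bank$models, 26)  # 250, 260, ..., 500 ms
  expect_equal(range(bank$train_times), c(250, 500))

  single <- train_bank(fx$att, window = c(300, 300), spec = spec)
  expect_length(single$models, 1)

  perc <- train_bank(fx$att, positive = "exploration", spec = spec)
  expect_equal(unname(perc$pair["positive"]), "exploration")

  expect_error(train_bank(fx$att, window = c(2000, 2100), spec = spec),
               class = "intrudetect_param_error")
})

test_that("generalization has the contracted shape and memorizes its own training data", {
  fx <- xt_fixture()
  spec <- fast_spec(n_estimators = 30, seed = 2)
  bank <- train_bank(fx$att, window = c(250, 400), spec = spec)
  n_att <- length(bank$models)

  pm <- generalize(bank, fx$att)  # test on the training task itself
  expect_equal(dim(pm$prob), c(nrow(fx$att$trials), n_att,
                               length(fx$att$times)))
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  # diagonal (matching timepoints) on intrusion training trials
  intr <- which(fx$att$trials$condition == "intrusion")
  tidx <- match(bank$train_times, fx$att$times)
  diag_p <- mean(vapply(seq_len(n_att),
                        function(k) mean(pm$prob[intr, k, tidx[k]]),
                        numeric(1)))
  expect_gt(diag_p, 0.5)

  other <- make_scalp_layout(8, seed = 1)
  tnt_bad <- series_epochs(rnorm(50), 100, n_channels = 8, layout = other)
  expect_error(generalize(bank, tnt_bad), class = "intrudetect_schema_error")
})

test_that("binarization is strict and threshold scales with the percentile", {
  fx <- xt_fixture()
  pm <- structure(list(prob = array(c(0.7, 0.6, 0.55, 0.6),
                                    dim = c(1, 2, 2)),
                       train_times = c(250, 260), test_times = c(0, 10),
                       trials = data.frame(report = 1)),
                  class = "probability_map")
  bm <- binarize(pm, 0.6)
  expect_equal(as.numeric(bm$map), c(1, 0, 0, 0))  # strict: ties are 0

  tnt_cfg <- small_tnt_cfg(n_items = 4, seed = 5)
  tnt <- simulate_tnt_dataset(tnt_cfg, fx$lay, fx$cfg)$epochs
  nul <- build_null(fx$att, tnt, window = c(300, 340),
                    spec = fast_spec(n_estimators = 20, seed = 3),
                    n_perm = 30, percentile = 95, seed = 9, max_trials = 6,
                    return_null = TRUE)
  expect_equal(nul$threshold,
               as.numeric(quantile(nul$null_samples, 0.95)))
  thr100 <- as.numeric(quantile(nul$null_samples, 1))
  expect_gte(thr100, nul$threshold)  # non-decreasing in percentile
  expect_error(build_null(fx$att, tnt, n_perm = 5),
               class = "intrudetect_param_error")
})

test_that("strength smoothing matches the convolution-sum oracle", {
  mk_bin <- function(v) {
    structure(list(map = array(v, dim = c(1, 1, length(v))),
                   threshold = 0.5, train_times = 250,
                   test_times = seq(0, by = 10, length.out = length(v)),
                   trials = data.frame(report = 1)),
              class = "binary_map")
  }
  # kernel halves at +/- fwhm/2 from the centre
  v <- numeric(101); v[51] <- 1
  st <- smooth_strength(mk_bin(v), fwhm_ms = 200)
  s <- st$strength[1, 1, ]
  expect_equal(s[61] / s[51], 0.5, tolerance = 1e-6)   # +100 ms = fwhm/2
  expect_equal(s[41] / s[51], 0.5, tolerance = 1e-6)
  expect_equal(sum(s), 1, tolerance = 1e-9)            # unit-sum kernel
  # direct convolution-sum oracle for the interior spike
  sigma <- 200 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / 10)  # documented 4-sigma truncation
  tt <- seq(-half, half) * 10
  kern <- exp(-tt^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  oracle <- numeric(101)
  for (j in seq_along(tt)) {
    pos <- 51 + (tt[j] / 10)
    if (pos >= 1 && pos <= 101) oracle[pos] <- oracle[pos] + kern[j]
  }
  expect_equal(s[30:70], oracle[30:70], tolerance = 1e-9)

  expect_true(all(smooth_strength(mk_bin(numeric(60)))$strength == 0))
  expect_error(smooth_strength(mk_bin(v), fwhm_ms = 0),
               class = "intrudetect_param_error")
})

test_that("AUC-matrix scoring selects the earliest best attention row", {
  mk_strength <- function(arr) {
    structure(list(strength = arr, attention_index = seq_len(dim(arr)[2]),
                   train_times = seq(250, by = 10,
                                     length.out = dim(arr)[2]),
                   test_times = seq(0, by = 10, length.out = dim(arr)[3]),
                   fwhm_ms = 200,
                   trials = data.frame(report = rep(c(1, 0),
                                                    each = dim(arr)[1] / 2))),
              class = "strength_timecourse")
  }
  # identical strengths for all trials: ties give AUC 0.5 everywhere
  flat <- array(0.3, dim = c(6, 3, 8))
  sc <- score_auc_matrix(mk_strength(flat))
  expect_true(all(sc$auc == 0.5))
  expect_equal(sc$selected_attention_index, 1)  # all rows tie: earliest wins

  # row 2 and row 3 identical and better than row 1: earliest of the tie
  arr <- array(0, dim = c(6, 3, 8))
  arr[1:3, 2, 5] <- 1; arr[1:3, 3, 5] <- 1
  sc2 <- score_auc_matrix(mk_strength(arr))
  expect_equal(sc2$selected_attention_index, 2)

  one_class <- mk_strength(flat)
  one_class$trials$report <- 1
  expect_error(score_auc_matrix(one_class),
               class = "intrudetect_single_class_error")
})

test_that("the cross-task pipeline is deterministic and amplitude-monotone", {
  run_one <- function(amp, seed) {
    coh <- binned_cohort(seed, n_participants = 1, amplitude = amp,
                         n_items = 8)
    decode_participant(coh$attention[[1]], coh$tnt[[1]],
                       spec = fast_spec(seed = 1), n_perm = 25, seed = 13,
                       null_max_trials = 8)
  }
  r1 <- run_one(12, 81)
  r2 <- run_one(12, 81)
  expect_identical(r1$prob$prob, r2$prob$prob)
  expect_identical(r1$null$threshold, r2$null$threshold)
  expect_identical(r1$strength$strength, r2$strength$strength)

  max_auc <- function(r) if (r$excluded) NA_real_ else max(r$scores$timecourse)
  lo <- mean(vapply(82:84, function(s) max_auc(run_one(0, s)), numeric(1)),
             na.rm = TRUE)
  hi <- mean(vapply(82:84, function(s) max_auc(run_one(12, s)), numeric(1)),
             na.rm = TRUE)
  expect_gt(hi, lo)
})
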