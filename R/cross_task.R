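#' Train a bank of per-timepoint classifiers on the attention task
#'
#' Fits one classifier per attention-task timepoint inside `window`
#' (inclusive of both endpoints on the binned grid), using all attention
#' trials of the condition pair — no cross-validation, because testing
#' happens on the other task. The default window 250-500 ms after the
#' central image covers the attentional-capture decoding peak.
#'
#' @param attention An attention-task `epoch_set`.
#' @param positive,negative Training condition pair. `"intrusion"` vs
#'   `"non_intrusion"` gives the attentional model; `"exploration"` vs
#'   `"non_intrusion"` the perceptual control model.
#' @param window `(start_ms, end_ms)` training window (default
#'   `c(250, 500)`).
#' @param spec A [classifier_spec()].
#' @return An object of class `classifier_bank`: list with `models` (one
#'   fitted classifier + standardizer per timepoint), `train_times` (ms),
#'   `channel_ids`, `pair`, `spec`.
#' @export
train_bank <- function(attention, positive = "intrusion",
                       negative = "non_intrusion", window = c(250, 500),
                       spec = classifier_spec()) {
  stopifnot(inherits(attention, "epoch_set"))
  idx <- time_index(attention$times, window[1], window[2])
  if (length(idx) == 0) stop_param("training window contains no timepoints")
  sel <- attention$trials$condition %in% c(positive, negative)
  if (!any(attention$trials$condition == positive) ||
      !any(attention$trials$condition == negative)) {
    stop_param("both training conditions must be present")
  }
  ep <- subset_trials(attention, sel)
  y <- as.integer(ep$trials$condition == positive)
  models <- lapply(seq_along(idx), function(k) {
    X <- matrix(ep$data[, , idx[k]], ncol = dim(ep$data)[2])
    fit_clf(X, y, spec, child_seed(spec$seed, 113L, k))
  })
  structure(list(models = models, train_times = attention$times[idx],
                 channel_ids = attention$layout$channel_ids,
                 pair = c(positive = positive, negative = negative),
                 spec = spec, window = window),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat(sprintf("<classifier_bank> %d models, %s vs %s, window %g..%g ms\n",
              length(x$models), x$pair["positive"], x$pair["negative"],
              min(x$train_times), max(x$train_times)))
  invisible(x)
}

#' Generalize a classifier bank across tasks
#'
#' Applies every trained attention-timepoint classifier to every timepoint
#' of every TNT epoch, yielding per-trial probability maps of intrusion.
#'
#' @param bank A [train_bank()] `classifier_bank`.
#' @param tnt A TNT `epoch_set` with the same channels and binning as the
#'   bank's training data.
#' @return An object of class `probability_map`: list with `prob`
#'   (`[n_trials, n_attention, n_tnt]` array in `[0, 1]`), `train_times`,
#'   `test_times`, `trials` (the TNT trial table).
#' @export
generalize <- function(bank, tnt) {
  stopifnot(inherits(bank, "classifier_bank"), inherits(tnt, "epoch_set"))
  if (!identical(bank$channel_ids, tnt$layout$channel_ids)) {
    stop_schema("TNT channels do not match the bank's training channels")
  }
  d <- dim(tnt$data)
  # stack trials x times into one matrix per model call (predict dominates
  # runtime; one call per model amortizes the dispatch overhead)
  flat <- matrix(aperm(tnt$data, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  prob <- array(0, dim = c(d[1], length(bank$models), d[3]))
  for (k in seq_along(bank$models)) {
    p <- predict_clf(bank$models[[k]], flat)
    prob[, k, ] <- matrix(p, d[1], d[3])
  }
  structure(list(prob = prob, train_times = bank$train_times,
                 test_times = tnt$times, trials = tnt$trials),
            class = "probability_map")
}

#' Permutation-null threshold for intrusion probabilities
#'
#' Estimates the null distribution of cross-task intrusion probabilities by
#' retraining the full classifier bank `n_perm` times with training labels
#' randomly permuted within the attention dataset, applying each null bank
#' to the TNT epochs, and pooling the resulting probabilities across
#' permutations, trials and both time axes. The detection threshold is the
#' given percentile of this pooled null.
#'
#' @param attention Attention-task `epoch_set`.
#' @param tnt TNT `epoch_set`.
#' @param positive,negative Training pair (as in [train_bank()]).
#' @param window Training window.
#' @param spec A [classifier_spec()].
#' @param n_perm Number of label permutations (default 200; >= 20).
#' @param percentile Null percentile defining the threshold (default 95).
#' @param seed Integer seed.
#' @param max_trials Optional cap on the number of TNT trials (a seeded
#'   subset) used to sample the pooled null — an unbiased subsample that
#'   bounds runtime; `NULL` (default) uses all trials.
#' @param return_null Keep the pooled null samples (`summary` always
#'   stored).
#' @return An object of class `null_threshold`: list with `threshold`,
#'   `percentile`, `n_perm`, `null_summary` (quantiles), and optionally
#'   `null_samples`.
#' @export
build_null <- function(attention, tnt, positive = "intrusion",
                       negative = "non_intrusion", window = c(250, 500),
                       spec = classifier_spec(), n_perm = 200,
                       percentile = 95, seed = 1L, max_trials = NULL,
                       return_null = FALSE) {
  if (n_perm < 20) stop_param("n_perm must be >= 20")
  if (n_perm < 100 / (100 - percentile)) {
    warning("n_perm is small for the requested percentile; threshold will be coarse")
  }
  idx <- time_index(attention$times, window[1], window[2])
  sel <- attention$trials$condition %in% c(positive, negative)
  ep <- subset_trials(attention, sel)
  y <- as.integer(ep$trials$condition == positive)
  tnt_use <- tnt
  if (!is.null(max_trials) && max_trials < dim(tnt$data)[1]) {
    pick <- with_seed(child_seed(seed, 127L),
                      sort(sample(dim(tnt$data)[1], max_trials)))
    tnt_use <- subset_trials(tnt, pick)
  }
  d <- dim(tnt_use$data)
  flat <- matrix(aperm(tnt_use$data, c(1, 3, 2)), nrow = d[1] * d[3],
                 ncol = d[2])
  nulls <- with_seed(child_seed(seed, 131L), {
    out <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      yb <- sample(y)
      probs <- lapply(seq_along(idx), function(k) {
        X <- matrix(ep$data[, , idx[k]], ncol = d[2])
        m <- fit_clf(X, yb, spec, child_seed(spec$seed, 137L, b, k))
        predict_clf(m, flat)
      })
      out[[b]] <- unlist(probs, use.names = FALSE)
    }
    unlist(out, use.names = FALSE)
  })
  thr <- as.numeric(stats::quantile(nulls, percentile / 100, type = 7))
  structure(list(threshold = thr, percentile = percentile, n_perm = n_perm,
                 pair = c(positive = positive, negative = negative),
                 window = window,
                 null_summary = stats::quantile(nulls, c(.05, .25, .5, .75,
                                                         .9, .95, .99, 1)),
                 n_null_samples = length(nulls),
                 null_samples = if (return_null) nulls else NULL),
            class = "null_threshold")
}

#' Threshold a probability map into a binary intrusion map
#'
#' Elementwise strict comparison: an entry is 1 when its probability
#' strictly exceeds the null threshold (ties are not detections).
#'
#' @param prob A [generalize()] `probability_map`.
#' @param thr A [build_null()] `null_threshold`, or a bare numeric
#'   threshold.
#' @return An object of class `binary_map` with the same shape and axes.
#' @export
binarize <- function(prob, thr) {
  stopifnot(inherits(prob, "probability_map"))
  tv <- if (inherits(thr, "null_threshold")) thr$threshold else as.numeric(thr)
  structure(list(map = (prob$prob > tv) * 1L, threshold = tv,
                 train_times = prob$train_times,
                 test_times = prob$test_times, trials = prob$trials),
            class = "binary_map")
}

# unit-sum Gaussian kernel sampled on the binned time grid
gaussian_kernel_ms <- function(fwhm_ms, bin_ms) {
  if (fwhm_ms <= 0) stop_param("fwhm must be positive")
  sigma <- fwhm_ms / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / bin_ms))
  tt <- seq(-half, half) * bin_ms
  k <- exp(-tt^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution with reflect padding at the edges
convolve_reflect <- function(x, kern) {
  half <- (length(kern) - 1) / 2
  n <- length(x)
  xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[(n - half):(n - 1)]))
  as.numeric(stats::filter(xp, kern, method = "convolution",
                           sides = 2)[(half + 1):(half + n)])
}

#' Smooth binary detections into memory-strength timecourses
#'
#' Convolves rows of the binary map along the TNT time axis with a unit-sum
#' Gaussian kernel (`sigma = fwhm / (2 sqrt(2 ln 2))`, truncated at 4 sigma,
#' reflect padding at the epoch edges), so strength is interpretable as a
#' local detected-event density in `[0, 1]`.
#'
#' @param binary A [binarize()] `binary_map`.
#' @param fwhm_ms Kernel full width at half maximum in ms (default 200).
#' @param attention_index Index (or indices) into the bank's training
#'   timepoints to smooth; `NULL` (default) smooths all rows.
#' @return An object of class `strength_timecourse`: list with `strength`
#'   (`[n_trials, n_attention_selected, n_tnt]`), `attention_index`,
#'   `train_times`, `test_times`, `fwhm_ms`, `trials`.
#' @export
smooth_strength <- function(binary, fwhm_ms = 200, attention_index = NULL) {
  stopifnot(inherits(binary, "binary_map"))
  n_att <- dim(binary$map)[2]
  attention_index <- attention_index %||% seq_len(n_att)
  if (any(attention_index < 1 | attention_index > n_att)) {
    stop_param("attention_index outside the trained window")
  }
  bin_ms <- if (length(binary$test_times) > 1) {
    binary$test_times[2] - binary$test_times[1]
  } else 1
  kern <- gaussian_kernel_ms(fwhm_ms, bin_ms)
  d <- dim(binary$map)
  out <- array(0, dim = c(d[1], length(attention_index), d[3]))
  for (i in seq_len(d[1])) {
    for (jj in seq_along(attention_index)) {
      out[i, jj, ] <- convolve_reflect(binary$map[i, attention_index[jj], ],
                                       kern)
    }
  }
  structure(list(strength = out, attention_index = attention_index,
                 train_times = binary$train_times[attention_index],
                 test_times = binary$test_times, fwhm_ms = fwhm_ms,
                 trials = binary$trials),
            class = "strength_timecourse")
}
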