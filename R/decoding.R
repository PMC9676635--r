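#' Per-timepoint cross-validated decoding of two conditions
#'
#' At each timepoint, the channel vector is the feature set; a classifier is
#' trained and tested within a stratified k-fold scheme (standardization and
#' class weights fit on the training split only) and performance is the AUC
#' of the held-out probabilities, averaged over folds.
#'
#' @param epochs An `epoch_set` containing both conditions.
#' @param positive,negative Condition labels; `positive` is scored as class
#'   1.
#' @param spec A [classifier_spec()].
#' @param n_folds Number of stratified folds (default 8).
#' @return An object of class `decoding_result`: list with `times`,
#'   `auc_mean` (per timepoint), `auc_per_fold` (`n_folds x n_times`),
#'   `n_folds`, `labels_used`.
#' @export
cv_auc_timecourse <- function(epochs, positive, negative, spec, n_folds = 8) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "classifier_spec"))
  sel <- epochs$trials$condition %in% c(positive, negative)
  ep <- subset_trials(epochs, sel)
  y <- as.integer(ep$trials$condition == positive)
  fold <- stratified_folds(y, n_folds, spec$seed)
  nt <- dim(ep$data)[3]
  aucs <- matrix(NA_real_, n_folds, nt)
  for (tp in seq_len(nt)) {
    X <- ep$data[, , tp, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = dim(ep$data)[2])
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      m <- fit_clf(X[tr, , drop = FALSE], y[tr], spec,
                   child_seed(spec$seed, 1L, tp, f))
      p <- predict_clf(m, X[!tr, , drop = FALSE])
      aucs[f, tp] <- auc(p, y[!tr])
    }
  }
  structure(list(times = ep$times, auc_mean = colMeans(aucs),
                 auc_per_fold = aucs, n_folds = n_folds,
                 labels_used = c(positive = positive, negative = negative)),
            class = "decoding_result")
}

#' Per-(frequency, timepoint) cross-validated decoding
#'
#' As [cv_auc_timecourse()] but on a Morlet time-frequency representation:
#' at each (frequency, timepoint) the features are the channel vector of
#' percent-change power.
#'
#' @param tfr A [morlet_tfr()] `tfr_epoch_set`.
#' @inheritParams cv_auc_timecourse
#' @return An object of class `tf_decoding_result`: list with `freqs`,
#'   `times`, `auc` (`n_freqs x n_times`), `n_folds`, `labels_used`.
#' @export
cv_auc_timefreq <- function(tfr, positive, negative, spec, n_folds = 8) {
  stopifnot(inherits(tfr, "tfr_epoch_set"), inherits(spec, "classifier_spec"))
  sel <- tfr$trials$condition %in% c(positive, negative)
  dat <- tfr$data[sel, , , , drop = FALSE]
  y <- as.integer(tfr$trials$condition[sel] == positive)
  fold <- stratified_folds(y, n_folds, spec$seed)
  nf <- dim(dat)[3]; nt <- dim(dat)[4]
  out <- matrix(NA_real_, nf, nt)
  for (k in seq_len(nf)) {
    for (tp in seq_len(nt)) {
      X <- matrix(dat[, , k, tp], ncol = dim(dat)[2])
      a <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        m <- fit_clf(X[tr, , drop = FALSE], y[tr], spec,
                     child_seed(spec$seed, k, tp, f))
        a[f] <- auc(predict_clf(m, X[!tr, , drop = FALSE]), y[!tr])
      }
      out[k, tp] <- mean(a)
    }
  }
  structure(list(freqs = tfr$freqs, times = tfr$times, auc = out,
                 n_folds = n_folds,
                 labels_used = c(positive = positive, negative = negative)),
            class = "tf_decoding_result")
}

#' Sensor-level condition contrast with max-statistic permutation correction
#'
#' Averages the signal over a time window, contrasts two conditions at every
#' channel with a t statistic, and corrects across channels by comparing
#' each |t| with the permutation distribution of the maximum |t|. When the
#' trial table has more than one participant the design is paired (per
#' participant condition means, one-sample t on the differences, sign-flip
#' permutations); otherwise it is a trialwise two-sample design with label
#' shuffles.
#'
#' @param epochs An `epoch_set`.
#' @param positive,negative Condition labels (contrast positive - negative).
#' @param window Averaging window in ms (default `c(280, 340)`, the window
#'   around the attentional decoding peak).
#' @param n_perm Number of permutations (default 2000; < 100 logs a
#'   warning but still runs).
#' @param alpha Familywise significance level (default 0.05).
#' @param seed Integer seed.
#' @return List with `t` (per channel), `p_corrected` (max-statistic
#'   corrected), `significant` (channel ids), `design`.
#' @export
sensor_contrast <- function(epochs, positive, negative, window = c(280, 340),
                            n_perm = 2000, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- time_index(epochs$times, window[1], window[2])
  if (length(idx) == 0) stop_param("window contains no samples")
  if (n_perm < 100) {
    warning("n_perm < 100: corrected p-values will be coarse")
  }
  sel <- epochs$trials$condition %in% c(positive, negative)
  ep <- subset_trials(epochs, sel)
  avg <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)  # trials x ch
  cond <- ep$trials$condition
  parts <- unique(ep$trials$participant)
  paired <- length(parts) > 1
  if (paired) {
    diffs <- t(vapply(parts, function(p) {
      pi <- ep$trials$participant == p
      colMeans(avg[pi & cond == positive, , drop = FALSE]) -
        colMeans(avg[pi & cond == negative, , drop = FALSE])
    }, numeric(ncol(avg))))
    tobs <- one_sample_t(diffs, 0)
    null_max <- with_seed(child_seed(seed, 83L), {
      vapply(seq_len(n_perm), function(b) {
        s <- sample(c(-1, 1), nrow(diffs), replace = TRUE)
        max(abs(one_sample_t(diffs * s, 0)))
      }, numeric(1))
    })
  } else {
    y <- cond == positive
    tobs <- two_sample_t(avg, y)
    null_max <- with_seed(child_seed(seed, 83L), {
      vapply(seq_len(n_perm), function(b) {
        max(abs(two_sample_t(avg, sample(y))))
      }, numeric(1))
    })
  }
  p_corr <- vapply(abs(tobs), function(tv) {
    (1 + sum(null_max >= tv)) / (1 + n_perm)
  }, numeric(1))
  list(t = stats::setNames(tobs, ep$layout$channel_ids),
       p_corrected = stats::setNames(p_corr, ep$layout$channel_ids),
       significant = ep$layout$channel_ids[p_corr <= alpha],
       design = if (paired) "paired" else "two_sample")
}

# columnwise one-sample t statistics vs mu0; zero-variance columns are
# clamped to +/- a large finite value (documented behaviour)
one_sample_t <- function(X, mu0) {
  n <- nrow(X)
  m <- colMeans(X) - mu0
  s <- sqrt(pmax((colSums(X^2) - n * (colMeans(X))^2) / (n - 1), 0))
  tt <- m / (s / sqrt(n))
  bad <- !is.finite(tt)
  if (any(bad)) tt[bad] <- sign(m[bad]) * 1e12
  tt[!is.finite(tt)] <- 0  # 0/0: mean exactly mu0 with zero variance
  tt
}

# columnwise Welch two-sample t statistics for logical group y
two_sample_t <- function(X, y) {
  a <- X[y, , drop = FALSE]; b <- X[!y, , drop = FALSE]
  va <- apply(a, 2, stats::var) / nrow(a)
  vb <- apply(b, 2, stats::var) / nrow(b)
  (colMeans(a) - colMeans(b)) / sqrt(va + vb)
}
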