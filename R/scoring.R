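#' Score strength timecourses against subjective reports
#'
#' For each (attention timepoint, TNT timepoint) cell, computes the AUC of
#' the across-trials strength values as predictions for the binary
#' subjective intrusion reports. The attention row whose maximum AUC is
#' largest (ties broken toward the earliest timepoint) is selected, and its
#' AUC timecourse over the suppression cue is the participant's decoding
#' performance timecourse.
#'
#' @param strength A [smooth_strength()] `strength_timecourse` covering all
#'   attention rows.
#' @param reports Binary vector of subjective reports, one per TNT trial;
#'   defaults to the `report` column of the strength's trial table. Both
#'   classes must be present (participants with single-class reports are
#'   excluded upstream).
#' @return An object of class `auc_matrix`: list with `auc`
#'   (`n_attention x n_tnt`), `selected_attention_index`, `selected_time_ms`,
#'   `timecourse` (the selected row), `train_times`, `test_times`.
#' @export
score_auc_matrix <- function(strength, reports = NULL) {
  stopifnot(inherits(strength, "strength_timecourse"))
  reports <- reports %||% strength$trials$report
  reports <- as.integer(as.logical(reports))
  if (length(unique(reports)) < 2) {
    stop(errorCondition("reports contain a single class; participant must be excluded",
                        class = c("intrudetect_single_class_error",
                                  "intrudetect_error")))
  }
  d <- dim(strength$strength)
  am <- matrix(NA_real_, d[2], d[3])
  for (j in seq_len(d[2])) {
    for (k in seq_len(d[3])) {
      am[j, k] <- auc(strength$strength[, j, k], reports)
    }
  }
  row_max <- apply(am, 1, max)
  sel <- which.max(row_max)  # which.max takes the earliest maximum
  structure(list(auc = am, selected_attention_index = sel,
                 selected_time_ms = strength$train_times[sel],
                 timecourse = am[sel, ], train_times = strength$train_times,
                 test_times = strength$test_times),
            class = "auc_matrix")
}

#' Group-level test of decoding timecourses against chance
#'
#' One-sample cluster-based permutation t test of per-participant AUC
#' timecourses against `mu0 = 0.5`, restricted to the window of interest
#' (default 200-3000 ms after cue onset).
#'
#' @param timecourses Matrix `participants x n_tnt` of selected-row AUC
#'   timecourses, or a list of [score_auc_matrix()] results.
#' @param times TNT time grid in ms (taken from the first `auc_matrix` when
#'   a list is given).
#' @param mu0 Chance level (default 0.5).
#' @param window Window of interest in ms (default `c(200, 3000)`).
#' @param n_perm,alpha_form,tail,seed Passed to
#'   [cluster_perm_one_sample()].
#' @return A `cluster_test_result` over the restricted time grid.
#' @export
group_auc_test <- function(timecourses, times = NULL, mu0 = 0.5,
                           window = c(200, 3000), n_perm = 20000,
                           alpha_form = 0.05, tail = "two_sided", seed = 1L) {
  if (is.list(timecourses) && !is.matrix(timecourses)) {
    times <- times %||% timecourses[[1]]$test_times
    timecourses <- do.call(rbind, lapply(timecourses, `[[`, "timecourse"))
  }
  if (is.null(times)) stop_param("times must be supplied")
  keep <- time_index(times, window[1], window[2])
  cluster_perm_one_sample(timecourses[, keep, drop = FALSE], mu0 = mu0,
                          n_perm = n_perm, alpha_form = alpha_form,
                          tail = tail, seed = seed, times = times[keep])
}

#' Compare attentional and perceptual model timecourses
#'
#' Paired cluster-based permutation test of the per-participant AUC
#' difference (attentional - perceptual) over the window of interest.
#'
#' @param attentional,perceptual Matrices `participants x n_tnt` (or lists
#'   of `auc_matrix`), paired by row/participant.
#' @inheritParams group_auc_test
#' @return A `cluster_test_result`.
#' @export
compare_models <- function(attentional, perceptual, times = NULL,
                           window = c(200, 3000), n_perm = 20000,
                           alpha_form = 0.05, tail = "two_sided", seed = 1L) {
  grab <- function(x) {
    if (is.list(x) && !is.matrix(x)) {
      times <<- times %||% x[[1]]$test_times
      do.call(rbind, lapply(x, `[[`, "timecourse"))
    } else x
  }
  a <- grab(attentional); b <- grab(perceptual)
  if (!all(dim(a) == dim(b))) {
    stop_schema("attentional and perceptual inputs must be paired (same shape)")
  }
  if (is.null(times)) stop_param("times must be supplied")
  keep <- time_index(times, window[1], window[2])
  cluster_perm_paired(a[, keep, drop = FALSE], b[, keep, drop = FALSE],
                      n_perm = n_perm, alpha_form = alpha_form, tail = tail,
                      seed = seed, times = times[keep])
}

#' Run the full cross-task decoding pipeline for one participant
#'
#' Trains the classifier bank on the participant's attention task,
#' generalizes to their TNT epochs, builds the permutation-null threshold,
#' binarizes, smooths all attention rows into strength timecourses, and
#' scores them against the subjective reports.
#'
#' @param attention,tnt The participant's `epoch_set`s (matching channels
#'   and binning).
#' @param positive,negative Training pair (attentional model by default).
#' @param window Training window (ms).
#' @param spec A [classifier_spec()].
#' @param n_perm,percentile Null-threshold settings (defaults 200 and 95).
#' @param fwhm_ms Strength-smoothing kernel FWHM (default 200 ms).
#' @param seed Integer seed for the permutation null.
#' @param null_max_trials Optional TNT-trial cap for the null (see
#'   [build_null()]).
#' @return List with `bank`, `prob`, `null`, `binary`, `strength`,
#'   `scores` (an `auc_matrix`), and `excluded` (TRUE with `scores = NULL`
#'   when the participant's reports contain a single class).
#' @export
decode_participant <- function(attention, tnt, positive = "intrusion",
                               negative = "non_intrusion",
                               window = c(250, 500),
                               spec = classifier_spec(), n_perm = 200,
                               percentile = 95, fwhm_ms = 200, seed = 1L,
                               null_max_trials = NULL) {
  bank <- train_bank(attention, positive, negative, window, spec)
  prob <- generalize(bank, tnt)
  nul <- build_null(attention, tnt, positive, negative, window, spec,
                    n_perm = n_perm, percentile = percentile, seed = seed,
                    max_trials = null_max_trials)
  bin <- binarize(prob, nul)
  strength <- smooth_strength(bin, fwhm_ms = fwhm_ms)
  scores <- tryCatch(score_auc_matrix(strength),
                     intrudetect_single_class_error = function(e) NULL)
  list(bank = bank, prob = prob, null = nul, binary = bin,
       strength = strength, scores = scores, excluded = is.null(scores))
}
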