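#' Simulate a full cohort (attention + TNT + recall) with ground truth
#'
#' Generates, for every participant, an attention-task epoch set (child
#' seed per participant) and the cohort's TNT epoch set, behavioral table
#' and recall table from one global seed.
#'
#' @param att_cfg An [attention_sim_config()] (its `seed` is re-derived per
#'   participant from `seed`).
#' @param tnt_cfg A [tnt_sim_config()].
#' @param seed Global integer seed.
#' @return List with `layout`, `attention` (named list of per-participant
#'   `epoch_set`s), `tnt` (named list of per-participant `epoch_set`s),
#'   `attention_truth`, `tnt_truth` (a `generation_truth`), `behavior`
#'   (TNT-phase table with 1-3 reports) and `recall` (final-recall table).
#' @export
simulate_cohort <- function(att_cfg, tnt_cfg, seed = 1L) {
  layout <- make_scalp_layout(att_cfg$n_channels, seed = child_seed(seed, 3L))
  att <- vector("list", tnt_cfg$n_participants)
  att_truth <- vector("list", tnt_cfg$n_participants)
  for (p in seq_len(tnt_cfg$n_participants)) {
    cfg_p <- att_cfg
    cfg_p$seed <- child_seed(seed, 5L, p)
    sim <- simulate_attention_dataset(cfg_p, layout, participant = p)
    att[[p]] <- sim$epochs
    sim$truth$participant <- p
    att_truth[[p]] <- sim$truth
  }
  tnt_cfg$seed <- child_seed(seed, 7L)
  tnt <- simulate_tnt_dataset(tnt_cfg, layout, att_cfg)
  recall <- simulate_recall_table(tnt_cfg, tnt$truth)
  behavior <- data.frame(participant = tnt$truth$prob$participant,
                         item = tnt$truth$prob$item,
                         condition = "NoThink",
                         block = tnt$truth$prob$block,
                         report = tnt$truth$prob$report_raw,
                         stringsAsFactors = FALSE)
  names(att) <- as.character(seq_len(tnt_cfg$n_participants))
  list(layout = layout, attention = att,
       tnt = split_by_participant(tnt$epochs),
       attention_truth = do.call(rbind, att_truth), tnt_truth = tnt$truth,
       behavior = behavior, recall = recall)
}

#' Run cross-task decoding for every participant of a cohort
#'
#' Applies [decode_participant()] to each participant (child seed per
#' participant) after optional time binning, and collects the group AUC
#' timecourses. Participants whose reports contain a single class are
#' excluded and listed.
#'
#' @param cohort A [simulate_cohort()] result (or a list with `attention`
#'   and `tnt` per-participant epoch lists).
#' @param bin_ms Optional bin width applied to both tasks before decoding
#'   (default NULL = no binning).
#' @param ... Passed to [decode_participant()].
#' @param seed Global seed for the permutation nulls.
#' @return List with `results` (per participant), `timecourses` (matrix of
#'   selected-row AUC timecourses for included participants), `times`,
#'   `excluded` (participant ids).
#' @export
decode_cohort <- function(cohort, bin_ms = NULL, seed = 1L, ...) {
  ids <- names(cohort$attention)
  results <- vector("list", length(ids))
  names(results) <- ids
  for (i in seq_along(ids)) {
    att <- cohort$attention[[i]]
    tnt <- cohort$tnt[[i]]
    if (!is.null(bin_ms)) {
      att <- bin_time(att, bin_ms)
      tnt <- bin_time(tnt, bin_ms)
    }
    results[[i]] <- decode_participant(att, tnt,
                                       seed = child_seed(seed, 11L, i), ...)
  }
  included <- !vapply(results, `[[`, logical(1), "excluded")
  tc <- do.call(rbind, lapply(results[included],
                              function(r) r$scores$timecourse))
  times <- if (any(included)) {
    results[[which(included)[1]]]$scores$test_times
  } else NULL
  list(results = results, timecourses = tc, times = times,
       excluded = ids[!included])
}
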