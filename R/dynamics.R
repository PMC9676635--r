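#' Binarize 1-3 intrusion ratings
#'
#' Ratings 2 and 3 (brief or vivid intrusion) become 1, rating 1 (no
#' intrusion) becomes 0. Already-binary tables pass through unchanged, so
#' the operation is idempotent.
#'
#' @param table Behavioral data.frame with a `report` column in `{1, 2, 3}`
#'   (or already `{0, 1}`).
#' @return The table with `report` binarized.
#' @export
binarize_reports <- function(table) {
  r <- table$report
  if (all(r %in% c(0, 1), na.rm = TRUE)) return(table)
  if (!all(r %in% c(1, 2, 3), na.rm = TRUE)) {
    stop_param("reports must be on the 1-3 scale (or already binary)")
  }
  table$report <- as.integer(r >= 2)
  table
}

#' Per-participant subjective intrusion slope
#'
#' For each participant, the proportion of reported intrusions per block
#' (`n_intrusion / (n_intrusion + n_non_intrusion)`) is correlated with the
#' block index; the Pearson correlation coefficient is the intrusion slope.
#' Zero-variance proportion series get slope 0 with a `degenerate` flag.
#'
#' @param table Behavioral data.frame with `participant`, `block` and
#'   binary `report` columns (TNT-phase rows).
#' @return An object of class `slope_result`: data.frame with `participant`,
#'   `slope`, `degenerate`; the blockwise proportion matrix is attached as
#'   attribute `"proportions"` (participants x blocks).
#' @export
intrusion_slope <- function(table) {
  table <- binarize_reports(table)
  if (all(is.na(table$report))) stop_param("no reports available")
  blocks <- sort(unique(table$block))
  if (length(blocks) < 2) stop_param("need at least 2 blocks")
  parts <- sort(unique(table$participant))
  prop <- matrix(NA_real_, length(parts), length(blocks),
                 dimnames = list(parts, blocks))
  for (i in seq_along(parts)) {
    for (j in seq_along(blocks)) {
      r <- table$report[table$participant == parts[i] &
                          table$block == blocks[j]]
      r <- r[!is.na(r)]
      if (length(r) > 0) prop[i, j] <- mean(r)
    }
  }
  res <- data.frame(participant = parts, slope = NA_real_,
                    degenerate = FALSE)
  for (i in seq_along(parts)) {
    ok <- !is.na(prop[i, ])
    if (sum(ok) < 2) stop_param("participant ", parts[i],
                                " has fewer than 2 blocks with reports")
    if (stats::sd(prop[i, ok]) < 1e-12) {
      res$slope[i] <- 0
      res$degenerate[i] <- TRUE
    } else {
      res$slope[i] <- stats::cor(prop[i, ok], blocks[ok])
    }
  }
  attr(res, "proportions") <- prop
  class(res) <- c("slope_result", "data.frame")
  res
}

#' Suppression-induced forgetting per participant
#'
#' SIF = % recall(Baseline) - % recall(No-Think), in percentage points.
#' Negative values (better No-Think recall) are allowed.
#'
#' @param table Final-recall data.frame with `participant`, `condition`
#'   (including `"NoThink"` and `"Baseline"`) and `recalled` columns.
#' @return data.frame with `participant`, `recall_baseline`,
#'   `recall_nothink` (percent) and `sif` (percentage points).
#' @export
sif <- function(table) {
  need <- c("NoThink", "Baseline")
  if (!all(need %in% table$condition)) {
    stop_param("recall table must contain NoThink and Baseline conditions")
  }
  parts <- sort(unique(table$participant))
  out <- do.call(rbind, lapply(parts, function(p) {
    tb <- table[table$participant == p, ]
    rb <- 100 * mean(tb$recalled[tb$condition == "Baseline"])
    rn <- 100 * mean(tb$recalled[tb$condition == "NoThink"])
    data.frame(participant = p, recall_baseline = rb, recall_nothink = rn,
               sif = rb - rn)
  }))
  rownames(out) <- NULL
  out
}

#' Decoded temporal intrusion slope for one participant
#'
#' At each TNT timepoint and block, the decoded intrusion proportion is
#' computed over the correctly classified trials only — those whose decoded
#' label at that timepoint matches their subjective report (true positives
#' and true negatives): `p = n_TP / (n_TP + n_TN)`. The slope at a
#' timepoint is the Pearson correlation of these proportions against block
#' index (blocks with no correctly classified trial are dropped pairwise;
#' fewer than `min_blocks` valid blocks flags the timepoint as missing).
#' The baseline slope is the mean slope over the baseline window.
#'
#' @param binary_sel Matrix `n_trials x n_tnt` — the selected attention
#'   row of each trial's binary map.
#' @param reports Binary subjective reports per trial.
#' @param blocks Block index per trial.
#' @param times TNT time grid (ms).
#' @param baseline_window Window defining the baseline slope (default
#'   `c(-200, 0)` ms).
#' @param min_blocks Minimum valid blocks for a Pearson fit (default 4).
#' @return An object of class `decoded_slope_result`: list with `times`,
#'   `slope` (per timepoint, NA where flagged missing), `baseline_slope`,
#'   `n_valid_blocks`.
#' @export
decoded_slope <- function(binary_sel, reports, blocks, times,
                          baseline_window = c(-200, 0), min_blocks = 4) {
  reports <- as.integer(as.logical(reports))
  stopifnot(nrow(binary_sel) == length(reports),
            length(blocks) == length(reports),
            ncol(binary_sel) == length(times))
  ub <- sort(unique(blocks))
  nt <- ncol(binary_sel)
  slope <- rep(NA_real_, nt)
  nval <- integer(nt)
  for (tp in seq_len(nt)) {
    dec <- binary_sel[, tp]
    correct <- dec == reports
    prop <- vapply(ub, function(b) {
      i <- blocks == b & correct
      if (!any(i)) return(NA_real_)
      mean(dec[i])  # among TP+TN, decoded 1 <=> TP
    }, numeric(1))
    ok <- !is.na(prop)
    nval[tp] <- sum(ok)
    if (sum(ok) >= min_blocks && stats::sd(prop[ok]) > 1e-12) {
      slope[tp] <- stats::cor(prop[ok], ub[ok])
    } else if (sum(ok) >= min_blocks) {
      slope[tp] <- 0
    }
  }
  bidx <- time_index(times, baseline_window[1], baseline_window[2])
  structure(list(times = times, slope = slope,
                 baseline_slope = mean(slope[bidx], na.rm = TRUE),
                 n_valid_blocks = nval),
            class = "decoded_slope_result")
}

#' Group test of decoded slopes against the baseline slope
#'
#' Paired cluster-based permutation test of per-participant decoded slopes
#' at each TNT timepoint against their baseline slope, over the window of
#' interest.
#'
#' @param slopes List of per-participant [decoded_slope()] results.
#' @param window Window of interest (default `c(200, 3000)` ms).
#' @param n_perm,alpha_form,tail,seed Passed to [cluster_perm_paired()].
#' @return A `cluster_test_result`.
#' @export
decoded_slope_test <- function(slopes, window = c(200, 3000), n_perm = 20000,
                               alpha_form = 0.05, tail = "two_sided",
                               seed = 1L) {
  times <- slopes[[1]]$times
  sl <- do.call(rbind, lapply(slopes, `[[`, "slope"))
  bl <- vapply(slopes, `[[`, numeric(1), "baseline_slope")
  keep <- time_index(times, window[1], window[2])
  sl <- sl[, keep, drop = FALSE]
  sl[is.na(sl)] <- 0  # flagged-missing timepoints contribute no signal
  cluster_perm_paired(sl, matrix(bl, nrow(sl), ncol(sl)), n_perm = n_perm,
                      alpha_form = alpha_form, tail = tail, seed = seed,
                      times = times[keep])
}

#' Spearman correlation between intrusion slope and SIF
#'
#' Reports the Spearman rho, a seeded percentile-bootstrap confidence
#' interval (default 90%, 10000 resamples) and a permutation p-value.
#'
#' @param slopes Per-participant slope vector.
#' @param sif_values Per-participant SIF vector (same order).
#' @param conf_level CI level (default 0.90).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param n_perm Permutations for the p-value (default 10000).
#' @param seed Integer seed.
#' @return List with `rho`, `ci` (length 2), `p_value`, `n`.
#' @export
slope_sif_correlation <- function(slopes, sif_values, conf_level = 0.90,
                                  n_boot = 10000, n_perm = 10000, seed = 1L) {
  n <- length(slopes)
  if (n < 4) stop_param("need at least 4 participants")
  if (length(sif_values) != n) stop_param("length mismatch")
  if (stats::sd(slopes) < 1e-12 || stats::sd(sif_values) < 1e-12) {
    stop(errorCondition("correlation undefined for constant input",
                        class = c("intrudetect_degenerate_error",
                                  "intrudetect_error")))
  }
  rho <- stats::cor(slopes, sif_values, method = "spearman")
  boot <- with_seed(child_seed(seed, 139L), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample(n, replace = TRUE)
      if (stats::sd(slopes[i]) < 1e-12 || stats::sd(sif_values[i]) < 1e-12) {
        return(NA_real_)
      }
      stats::cor(slopes[i], sif_values[i], method = "spearman")
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE)
  pnull <- with_seed(child_seed(seed, 149L), {
    vapply(seq_len(n_perm), function(b) {
      stats::cor(slopes, sample(sif_values), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(pnull) >= abs(rho))) / (1 + n_perm)
  list(rho = rho, ci = as.numeric(ci), p_value = p, n = n,
       conf_level = conf_level)
}

#' Label item states from the future course of reports
#'
#' An item that intrudes in block N is a *stable* intrusive memory if it
#' intrudes again in any later block, and a *regulated* intrusive memory if
#' it never does. A non-intrusive item in block N is *stable* if it never
#' intrudes later and a *relapse* if it does. The last block has no future
#' and is labeled `terminal`.
#'
#' @param table Behavioral data.frame with `participant`, `item`, `block`
#'   and binary `report`; every item must have a complete block sequence.
#' @return data.frame (participant, item, block, report, state) with state
#'   in `stable_intrusive`, `regulated_intrusive`, `stable_nonintrusive`,
#'   `relapse_nonintrusive`, `terminal`.
#' @export
label_states <- function(table) {
  table <- binarize_reports(table)
  blocks <- sort(unique(table$block))
  if (!identical(blocks, seq(min(blocks), max(blocks)))) {
    stop_param("block sequence has gaps")
  }
  out <- table[order(table$participant, table$item, table$block),
               c("participant", "item", "block", "report")]
  key <- interaction(out$participant, out$item, drop = TRUE)
  for (g in split(seq_len(nrow(out)), key)) {
    if (!identical(sort(out$block[g]), blocks)) {
      stop_param("every item needs a complete block sequence")
    }
  }
  out$state <- NA_character_
  last <- max(blocks)
  for (g in split(seq_len(nrow(out)), key)) {
    r <- out$report[g]
    for (j in seq_along(g)) {
      b <- out$block[g[j]]
      if (b == last) {
        out$state[g[j]] <- "terminal"
      } else {
        future_intrusion <- any(r[out$block[g] > b] == 1)
        out$state[g[j]] <- if (r[j] == 1) {
          if (future_intrusion) "stable_intrusive" else "regulated_intrusive"
        } else {
          if (future_intrusion) "relapse_nonintrusive" else "stable_nonintrusive"
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Item-state contrast of memory-strength timecourses
#'
#' At each TNT timepoint, fits a linear mixed model
#' `strength ~ state + (1 | participant) + (1 | item)` (REML, Satterthwaite
#' degrees of freedom) and takes the t value of the state effect; the
#' resulting t map enters a cluster-based permutation test in which state
#' labels are shuffled within participant x block strata. Timepoints where
#' the LME fails to converge fall back to a participant-aggregated paired t
#' statistic (logged via `message`).
#'
#' @param strength_rows Matrix `n_trials x n_tnt` of selected-row strength
#'   timecourses (rows align with `meta`).
#' @param meta data.frame with `participant`, `item`, `block` per trial.
#' @param states A [label_states()] data.frame.
#' @param contrast `"intrusive"` (regulated vs stable intrusive) or
#'   `"nonintrusive"` (stable vs relapse non-intrusive).
#' @param times TNT time grid (ms).
#' @param window Window of interest (default `c(200, 3000)`).
#' @param n_perm Label permutations (default 1000).
#' @param alpha_form,tail,seed As in [cluster_perm_tmap()].
#' @return A `cluster_test_result`; the observed t map is in `$t`.
#' @export
state_contrast <- function(strength_rows, meta, states,
                           contrast = c("intrusive", "nonintrusive"),
                           times, window = c(200, 3000), n_perm = 1000,
                           alpha_form = 0.05, tail = "two_sided", seed = 1L) {
  contrast <- match.arg(contrast)
  lv <- if (contrast == "intrusive") {
    c("stable_intrusive", "regulated_intrusive")
  } else {
    c("stable_nonintrusive", "relapse_nonintrusive")
  }
  mkey <- paste(meta$participant, meta$item, meta$block)
  skey <- paste(states$participant, states$item, states$block)
  st <- states$state[match(mkey, skey)]
  keep_tr <- which(st %in% lv)
  if (length(unique(meta$item[keep_tr][st[keep_tr] == lv[1]])) < 2 ||
      length(unique(meta$item[keep_tr][st[keep_tr] == lv[2]])) < 2) {
    stop_param("each state needs at least 2 items")
  }
  keep_tp <- time_index(times, window[1], window[2])
  Y <- strength_rows[keep_tr, keep_tp, drop = FALSE]
  md <- meta[keep_tr, , drop = FALSE]
  lab <- factor(st[keep_tr], levels = lv)
  tmap_fn <- function(data, labels) {
    vapply(seq_len(ncol(data$Y)), function(tp) {
      df <- data.frame(y = data$Y[, tp], state = labels,
                       participant = factor(data$md$participant),
                       item = factor(data$md$item))
      tv <- tryCatch({
        fit <- suppressMessages(suppressWarnings(
          lmerTest::lmer(y ~ state + (1 | participant) + (1 | item),
                         data = df, REML = TRUE)))
        stats::coef(summary(fit))[2, "t value"]
      }, error = function(e) NA_real_)
      if (is.na(tv)) {
        # fallback: participant-aggregated paired t
        agg <- tapply(df$y, list(df$participant, df$state), mean)
        dd <- agg[, 2] - agg[, 1]
        dd <- dd[!is.na(dd)]
        tv <- if (length(dd) >= 2 && stats::sd(dd) > 0) {
          mean(dd) / (stats::sd(dd) / sqrt(length(dd)))
        } else 0
        message("state_contrast: LME fallback to paired t at a timepoint")
      }
      tv
    }, numeric(1))
  }
  strata <- factor(paste(md$participant, md$block))
  cluster_perm_tmap(tmap_fn, list(Y = Y, md = md), lab, n_perm = n_perm,
                    strata = strata, alpha_form = alpha_form, tail = tail,
                    seed = seed, times = times[keep_tp])
}
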