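#' Cluster-based permutation one-sample t test over time
#'
#' Forms per-timepoint one-sample t statistics against `mu0`, groups
#' contiguous suprathreshold timepoints into clusters (separately for
#' positive and negative t when two-sided), sums the t values within each
#' cluster (cluster mass), and compares each observed mass with the
#' permutation distribution of the maximum cluster mass obtained by random
#' per-participant sign flips of `data - mu0`. p-values include the identity
#' permutation: `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param data Numeric matrix `participants x timepoints` (>= 2 rows).
#' @param mu0 Null value (default 0).
#' @param n_perm Number of sign-flip permutations (default 20000).
#' @param alpha_form Cluster-forming p threshold on the pointwise t test
#'   (default 0.05).
#' @param tail `"two_sided"` (default) or `"one_sided_greater"`.
#' @param seed Integer seed.
#' @param times Optional time grid (ms) used to report cluster extents.
#' @return An object of class `cluster_test_result`: data.frame `clusters`
#'   with `start_index`, `end_index`, `start_ms`, `end_ms`, `mass`,
#'   `p_value`, plus fields `t`, `n_perm`, `alpha_form`, `tail`.
#' @export
cluster_perm_one_sample <- function(data, mu0 = 0, n_perm = 20000,
                                    alpha_form = 0.05, tail = "two_sided",
                                    seed = 1L, times = NULL) {
  tail <- match.arg(tail, c("two_sided", "one_sided_greater"))
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) stop_param("need at least 2 participants")
  X <- data - mu0
  tcrit <- t_threshold(n - 1, alpha_form, tail)
  tobs <- one_sample_t(X, 0)
  obs <- find_clusters(tobs, tcrit, tail)
  # vectorized sign-flip null of the maximum cluster mass
  null_max <- with_seed(child_seed(seed, 97L), {
    vapply(seq_len(n_perm), function(b) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tp <- one_sample_t(X * s, 0)
      cl <- find_clusters(tp, tcrit, tail)
      if (nrow(cl) == 0) 0 else max(abs(cl$mass))
    }, numeric(1))
  })
  if (nrow(obs) > 0) {
    obs$p_value <- vapply(abs(obs$mass), function(m) {
      (1 + sum(null_max >= m)) / (1 + n_perm)
    }, numeric(1))
  } else {
    obs$p_value <- numeric(0)
  }
  if (!is.null(times) && nrow(obs) > 0) {
    obs$start_ms <- times[obs$start_index]
    obs$end_ms <- times[obs$end_index]
  }
  structure(list(clusters = obs, t = tobs, n_perm = n_perm,
                 alpha_form = alpha_form, tail = tail, mu0 = mu0,
                 times = times),
            class = "cluster_test_result")
}

#' Cluster-based permutation paired t test
#'
#' Equivalent to [cluster_perm_one_sample()] on `a - b` with `mu0 = 0`.
#'
#' @param a,b Numeric matrices `participants x timepoints` of equal shape,
#'   paired by row.
#' @inheritParams cluster_perm_one_sample
#' @return A `cluster_test_result`.
#' @export
cluster_perm_paired <- function(a, b, n_perm = 20000, alpha_form = 0.05,
                                tail = "two_sided", seed = 1L, times = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop_schema("a and b must have identical shape")
  cluster_perm_one_sample(a - b, mu0 = 0, n_perm = n_perm,
                          alpha_form = alpha_form, tail = tail, seed = seed,
                          times = times)
}

#' Cluster-based permutation test for an arbitrary t-map function
#'
#' Computes an observed per-timepoint t map with `tmap_fn(data, labels)`,
#' then builds the null by recomputing the map with labels permuted within
#' `strata`. Clustering and p-values as in [cluster_perm_one_sample()].
#' Permutations on which `tmap_fn` fails are dropped and counted; more than
#' 10% failures is an error.
#'
#' @param tmap_fn Function `(data, labels) -> numeric t vector`; must be
#'   deterministic. Its `df` attribute (if any) is used for the
#'   cluster-forming threshold, else a normal approximation is used.
#' @param data Arbitrary object passed through to `tmap_fn`.
#' @param labels Vector of labels to permute.
#' @param n_perm Number of permutations (default 1000).
#' @param strata Optional factor; labels are shuffled within its levels.
#' @inheritParams cluster_perm_one_sample
#' @return A `cluster_test_result` (with `n_perm_used` after drops).
#' @export
cluster_perm_tmap <- function(tmap_fn, data, labels, n_perm = 1000,
                              strata = NULL, alpha_form = 0.05,
                              tail = "two_sided", seed = 1L, times = NULL) {
  tail <- match.arg(tail, c("two_sided", "one_sided_greater"))
  tobs <- tmap_fn(data, labels)
  df <- attr(tobs, "df") %||% Inf
  tcrit <- t_threshold(df, alpha_form, tail)
  obs <- find_clusters(as.numeric(tobs), tcrit, tail)
  perm_labels <- function(lab) {
    if (is.null(strata)) return(sample(lab))
    out <- lab
    for (lv in split(seq_along(lab), strata)) out[lv] <- lab[sample(lv)]
    out
  }
  dropped <- 0L
  null_max <- with_seed(child_seed(seed, 101L), {
    vals <- numeric(0)
    for (b in seq_len(n_perm)) {
      lb <- perm_labels(labels)
      tp <- tryCatch(as.numeric(tmap_fn(data, lb)), error = function(e) NULL)
      if (is.null(tp) || anyNA(tp)) {
        dropped <- dropped + 1L
        next
      }
      cl <- find_clusters(tp, tcrit, tail)
      vals <- c(vals, if (nrow(cl) == 0) 0 else max(abs(cl$mass)))
    }
    vals
  })
  if (dropped > 0.1 * n_perm) {
    stop("more than 10% of permutations failed in cluster_perm_tmap")
  }
  if (dropped > 0) {
    message(sprintf("cluster_perm_tmap: dropped %d failed permutations", dropped))
  }
  n_used <- length(null_max)
  if (nrow(obs) > 0) {
    obs$p_value <- vapply(abs(obs$mass), function(m) {
      (1 + sum(null_max >= m)) / (1 + n_used)
    }, numeric(1))
  } else {
    obs$p_value <- numeric(0)
  }
  if (!is.null(times) && nrow(obs) > 0) {
    obs$start_ms <- times[obs$start_index]
    obs$end_ms <- times[obs$end_index]
  }
  structure(list(clusters = obs, t = as.numeric(tobs), n_perm = n_perm,
                 n_perm_used = n_used, n_dropped = dropped,
                 alpha_form = alpha_form, tail = tail, times = times),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d permutations (%s)\n",
              nrow(x$clusters), x$n_perm, x$tail))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

# cluster-forming t threshold for the pointwise test
t_threshold <- function(df, alpha_form, tail) {
  if (tail == "two_sided") {
    if (is.finite(df)) stats::qt(1 - alpha_form / 2, df) else stats::qnorm(1 - alpha_form / 2)
  } else {
    if (is.finite(df)) stats::qt(1 - alpha_form, df) else stats::qnorm(1 - alpha_form)
  }
}

# contiguous suprathreshold runs; two-sided forms positive and negative
# clusters separately; mass = sum of t inside the run
find_clusters <- function(tvec, tcrit, tail) {
  res <- list()
  collect <- function(mask) {
    if (!any(mask)) return(NULL)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    data.frame(start_index = starts[keep], end_index = ends[keep])
  }
  pos <- collect(tvec > tcrit)
  if (!is.null(pos)) {
    pos$mass <- vapply(seq_len(nrow(pos)), function(i) {
      sum(tvec[pos$start_index[i]:pos$end_index[i]])
    }, numeric(1))
    res$pos <- pos
  }
  if (tail == "two_sided") {
    neg <- collect(tvec < -tcrit)
    if (!is.null(neg)) {
      neg$mass <- vapply(seq_len(nrow(neg)), function(i) {
        sum(tvec[neg$start_index[i]:neg$end_index[i]])
      }, numeric(1))
      res$neg <- neg
    }
  }
  if (length(res) == 0) {
    return(data.frame(start_index = integer(), end_index = integer(),
                      mass = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start_index), , drop = FALSE]
}
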