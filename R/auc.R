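#' Area under the ROC curve
#'
#' Computes the AUC as the normalized Mann-Whitney U statistic: the
#' probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counted 0.5. Implemented with midranks, so it
#' agrees exactly with brute-force pairwise counting.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return AUC in `[0, 1]`. Satisfies `auc(s, y) + auc(-s, y) == 1` exactly.
#' @export
#' @examples
#' auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))  # 0.75
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop_param("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop(errorCondition("AUC undefined: both classes must be present",
                        class = c("intrudetect_single_class_error",
                                  "intrudetect_error")))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
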