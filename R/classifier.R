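#' Classifier specification
#'
#' Random-forest classifier settings used by every decoding routine: 50
#' trees, inverse-frequency ("balanced") class weights, and feature-wise
#' standardization fit on the training split only.
#'
#' @param model Only `"random_forest"` is implemented.
#' @param n_estimators Number of trees (default 50).
#' @param class_weight `"balanced"` (inverse class frequency) or `"none"`.
#' @param standardize Z-score features using training-split means/sds
#'   (default `TRUE`).
#' @param seed Integer seed; each fitted model derives its own child seed
#'   from this plus its timepoint/fold/permutation indices, so results are
#'   reproducible regardless of evaluation order.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(model = "random_forest", n_estimators = 50,
                            class_weight = "balanced", standardize = TRUE,
                            seed = 1L) {
  model <- match.arg(model, "random_forest")
  class_weight <- match.arg(class_weight, c("balanced", "none"))
  if (n_estimators < 1) stop_config("n_estimators must be >= 1")
  structure(list(model = model, n_estimators = as.integer(n_estimators),
                 class_weight = class_weight, standardize = standardize,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Fit one standardizer + random forest on X [n x p], y in {0, 1}.
# `seed` fixes the forest's bootstrap/feature sampling.
fit_clf <- function(X, y, spec, seed) {
  y <- as.integer(y)
  mu <- sdv <- NULL
  if (spec$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  }
  classwt <- NULL
  if (spec$class_weight == "balanced") {
    tb <- table(factor(y, levels = c(0, 1)))
    classwt <- as.numeric(length(y) / (2 * tb))
    names(classwt) <- names(tb)
  }
  fit <- with_seed(seed, {
    randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                               ntree = spec$n_estimators, classwt = classwt)
  })
  list(fit = fit, mu = mu, sd = sdv)
}

# Probability of the positive class for new rows, applying the training
# standardization.
predict_clf <- function(model, Xnew) {
  if (!is.null(model$mu)) {
    Xnew <- sweep(sweep(Xnew, 2, model$mu, "-"), 2, model$sd, "/")
  }
  as.numeric(stats::predict(model$fit, newdata = Xnew, type = "prob")[, "1"])
}

# Seeded stratified fold assignment: within each class, trials are dealt
# into folds in a seeded random order. Computed once per dataset so the
# folds (and hence AUCs) are fixed by the seed alone.
stratified_folds <- function(labels, n_folds, seed) {
  labels <- as.integer(as.logical(labels))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop(errorCondition(paste0("class ", cl, " has ", length(idx),
                                 " trials; need at least one per each of ",
                                 n_folds, " folds"),
                          class = c("intrudetect_fold_error",
                                    "intrudetect_error")))
    }
    ord <- with_seed(child_seed(seed, 71L, cl), sample(idx))
    fold[ord] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}
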