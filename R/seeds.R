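#' Derive a child seed from a global seed
#'
#' Mixes the global seed with one or more integer keys into a new seed in
#' `[1, 2^31 - 2]`. Every randomized stage of the pipeline draws its RNG
#' state from a named child seed so that stages are reproducible
#' independently of the order in which they run.
#'
#' @param seed Integer global seed.
#' @param ... Integer keys (e.g. timepoint index, fold index, permutation
#'   index) identifying the consumer.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, 3, 5)
child_seed <- function(seed, ...) {
  keys <- c(seed, unlist(list(...), use.names = FALSE))
  stopifnot(length(keys) >= 1, all(is.finite(keys)))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; products stay exact in doubles
  x <- 0
  for (k in keys) {
    x <- (x * 69069 + (as.double(k) %% m) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps library code from disturbing user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("intrudetect_config_error",
                                             "intrudetect_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("intrudetect_param_error",
                                             "intrudetect_error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("intrudetect_schema_error",
                                             "intrudetect_error")))
}
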