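test_that("one-sample cluster test reproduces the exhaustive sign-flip p", {
  # n = 6 identical-sign values at one timepoint: only the identity pattern
  # reaches the observed mass, so the exact one-sided p is 1/64
  d <- matrix(1:6, ncol = 1)
  p_exact <- exhaustive_cluster_p(d, 0, tail = "one_sided_greater")
  expect_equal(p_exact, 1 / 64)
  res <- cluster_perm_one_sample(d, 0, n_perm = 4000,
                                 tail = "one_sided_greater", seed = 2)
  expect_equal(nrow(res$clusters), 1)
  band <- qbinom(c(0.0005, 0.9995), 4000, p_exact) / 4000
  expect_gte(res$clusters$p_value, band[1])
  expect_lte(res$clusters$p_value, band[2] + 1 / 4000)
})

test_that("degenerate and null inputs give empty cluster lists", {
  d <- matrix(5, nrow = 4, ncol = 10)
  res <- cluster_perm_one_sample(d, mu0 = 5, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
})

test_that("p-values are invariant to a common shift of data and mu0", {
  set.seed(33)
  d <- matrix(rnorm(8 * 12, mean = 0.4), 8, 12)
  r1 <- cluster_perm_one_sample(d, 0, n_perm = 500, seed = 5)
  r2 <- cluster_perm_one_sample(d + 3, 3, n_perm = 500, seed = 5)
  expect_equal(r1$clusters, r2$clusters, tolerance = 1e-12)
})

test_that("paired test is antisymmetric and detects a uniform shift", {
  set.seed(44)
  a <- matrix(rnorm(6 * 15), 6, 15)
  expect_equal(nrow(cluster_perm_paired(a, a, n_perm = 200, seed = 1)$clusters),
               0)
  b <- a - 2  # large uniform shift: one full-length cluster
  r <- cluster_perm_paired(a, b, n_perm = 500, seed = 1)
  expect_equal(nrow(r$clusters), 1)
  expect_equal(c(r$clusters$start_index, r$clusters$end_index), c(1, 15))
  # constant difference: identity and the all-flipped pattern share the
  # maximal |mass|, so the exact two-sided p is 2/2^6
  expect_lt(r$clusters$p_value, 0.05)
  r_sw <- cluster_perm_paired(b, a, n_perm = 500, seed = 1)
  expect_equal(r_sw$clusters$mass, -r$clusters$mass, tolerance = 1e-12)
  expect_equal(r_sw$clusters$p_value, r$clusters$p_value)
  expect_error(cluster_perm_paired(a, a[, 1:3]),
               class = "intrudetect_schema_error")
})

test_that("cluster times are reported on the supplied grid", {
  set.seed(55)
  d <- matrix(rnorm(10 * 20), 10, 20)
  d[, 8:12] <- d[, 8:12] + 2
  tms <- seq(0, by = 50, length.out = 20)
  r <- cluster_perm_one_sample(d, 0, n_perm = 500, seed = 3, times = tms)
  expect_true(all(r$clusters$start_ms %in% tms))
  big <- r$clusters[which.max(abs(r$clusters$mass)), ]
  expect_lte(big$start_ms, 350)
  expect_gte(big$end_ms, 400)
})

test_that("t-map permutation engine respects strata and failure limits", {
  set.seed(66)
  n <- 40
  labels <- rep(c("x", "y"), n / 2)
  strata <- factor(rep(1:4, each = n / 4))
  data <- matrix(rnorm(n * 6), n, 6)
  data[labels == "x", 3:4] <- data[labels == "x", 3:4] + 1.5
  tmap <- function(d, lab) {
    vapply(seq_len(ncol(d)), function(j) {
      unname(stats::t.test(d[lab == "x", j], d[lab == "y", j])$statistic)
    }, numeric(1))
  }
  r <- cluster_perm_tmap(tmap, data, labels, n_perm = 300, strata = strata,
                         seed = 7)
  expect_gte(nrow(r$clusters), 1)
  expect_lt(min(r$clusters$p_value), 0.05)

  # within-stratum shuffles preserve per-stratum label counts
  cnt <- table(strata, labels)
  perm_check <- function(d, lab) {
    expect_equal(table(strata, lab), cnt, ignore_attr = TRUE)
    tmap(d, lab)
  }
  invisible(cluster_perm_tmap(perm_check, data, labels, n_perm = 10,
                              strata = strata, seed = 8))

  # single timepoint reduces to a plain permutation test on one statistic
  r1 <- cluster_perm_tmap(tmap, data[, 3, drop = FALSE], labels, n_perm = 300,
                          seed = 9)
  expect_lte(nrow(r1$clusters), 1)

  calls <- 0L
  flaky <- function(d, lab) {
    calls <<- calls + 1L
    if (calls > 1 && calls %% 2 == 0) stop("boom")
    tmap(d, lab)
  }
  expect_error(suppressMessages(
    cluster_perm_tmap(flaky, data, labels, n_perm = 100, seed = 10)),
    "10%")
})
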