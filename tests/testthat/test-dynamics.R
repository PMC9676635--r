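test_that("report binarization maps 2-3 to intrusion and is idempotent", {
  tb <- data.frame(participant = 1, item = 1:6, block = 1,
                   report = c(1, 2, 3, 1, 2, 1))
  b <- binarize_reports(tb)
  expect_equal(b$report, c(0, 1, 1, 0, 1, 0))
  expect_identical(binarize_reports(b), b)
  expect_error(binarize_reports(data.frame(report = c(0.5, 4))),
               class = "intrudetect_param_error")
})

test_that("subjective intrusion slope is the Pearson r of block proportions", {
  mk <- function(props, ni = 40) {
    do.call(rbind, lapply(seq_along(props), function(b) {
      n1 <- round(props[b] * ni)
      data.frame(participant = 1, item = seq_len(ni), block = b,
                 report = c(rep(1, n1), rep(0, ni - n1)))
    }))
  }
  sl <- intrusion_slope(mk(seq(0.8, 0.1, by = -0.1)))  # exact with 40 items
  expect_equal(sl$slope, -1)
  expect_false(sl$degenerate)
  prop <- attr(sl, "proportions")
  expect_equal(as.numeric(prop[1, ]), seq(0.8, 0.1, by = -0.1))

  const <- intrusion_slope(mk(rep(0.25, 8), ni = 24))  # 6 of 24 per block
  expect_equal(const$slope, 0)
  expect_true(const$degenerate)
  expect_equal(as.numeric(attr(const, "proportions")[1, 1]), 6 / 24)

  expect_error(intrusion_slope(mk(0.5)), class = "intrudetect_param_error")
})

test_that("SIF is the baseline-minus-NoThink recall difference in points", {
  mk <- function(nb, nn) {
    data.frame(participant = 1, item = rep(1:20, 2),
               condition = rep(c("Baseline", "NoThink"), each = 20),
               recalled = c(rep(1, nb), rep(0, 20 - nb),
                            rep(1, nn), rep(0, 20 - nn)))
  }
  expect_equal(sif(mk(17, 15))$sif, 10)
  expect_equal(sif(mk(12, 12))$sif, 0)
  expect_equal(sif(mk(10, 14))$sif, -20)  # better NoThink recall is allowed
  expect_error(sif(data.frame(participant = 1, condition = "Think",
                              recalled = 1)),
               class = "intrudetect_param_error")
})

test_that("decoded slope reduces to the subjective slope for perfect decoding", {
  set.seed(77)
  nb <- 8; ni <- 24
  blocks <- rep(1:nb, each = ni)
  props <- seq(0.8, 0.1, length.out = nb)
  reports <- unlist(lapply(1:nb, function(b) {
    n1 <- round(props[b] * ni); sample(c(rep(1, n1), rep(0, ni - n1)))
  }))
  times <- seq(-200, 1000, by = 50)
  perfect <- matrix(reports, nrow = length(reports), ncol = length(times))
  ds <- decoded_slope(perfect, reports, blocks, times)
  tb <- data.frame(participant = 1, item = rep(1:ni, nb), block = blocks,
                   report = reports)
  subj <- intrusion_slope(tb)$slope
  expect_true(all(abs(ds$slope - subj) < 1e-12))
  expect_equal(ds$baseline_slope, subj, tolerance = 1e-12)

  # random decoding of block-balanced reports carries no trend on average
  # (report proportions are held exactly at 0.5 per block so the only
  # variation left is the decoder noise)
  flat_reports <- unlist(lapply(1:nb, function(b) sample(rep(0:1, ni / 2))))
  rnd <- matrix(rbinom(length(reports) * length(times), 1, 0.5),
                nrow = length(reports))
  dr <- decoded_slope(rnd, flat_reports, blocks, times)
  expect_lt(abs(mean(dr$slope, na.rm = TRUE)), 0.25)
})

test_that("slope-SIF correlation reports rho, CI and permutation p", {
  x <- seq(-1, 1, length.out = 12)
  r <- slope_sif_correlation(x, -x, n_boot = 200, n_perm = 200, seed = 1)
  expect_equal(r$rho, -1)
  expect_lt(r$p_value, 0.02)
  expect_true(r$ci[1] <= r$rho + 1e-9)
  expect_error(slope_sif_correlation(rep(1, 10), rnorm(10)),
               class = "intrudetect_degenerate_error")
  expect_error(slope_sif_correlation(1:3, 3:1),
               class = "intrudetect_param_error")
})

test_that("item states follow the future course of reports", {
  mk <- function(r) data.frame(participant = 1, item = 1, block = 1:8,
                               report = r)
  st <- label_states(mk(c(1, 1, 0, 0, 0, 0, 0, 0)))
  expect_equal(st$state[1], "stable_intrusive")
  expect_equal(st$state[2], "regulated_intrusive")
  expect_equal(st$state[8], "terminal")

  st2 <- label_states(mk(c(0, 0, 0, 0, 0, 0, 0, 1)))
  expect_equal(st2$state[1:7], rep("relapse_nonintrusive", 7))

  # every non-terminal (item, block) gets exactly one state
  set.seed(88)
  tb <- expand.grid(participant = 1:3, item = 1:5, block = 1:8)
  tb$report <- rbinom(nrow(tb), 1, 0.4)
  states <- label_states(tb)
  nonterm <- states[states$block < 8, ]
  expect_true(all(nonterm$state %in% c("stable_intrusive",
                                       "regulated_intrusive",
                                       "stable_nonintrusive",
                                       "relapse_nonintrusive")))
  expect_equal(nrow(nonterm), 3 * 5 * 7)

  bad <- tb[tb$block != 4, ]
  expect_error(label_states(bad), class = "intrudetect_param_error")
})

test_that("state contrast finds a planted strength reduction in regulated items", {
  set.seed(99)
  np <- 6; ni <- 12; nb <- 4
  meta <- expand.grid(item = 1:ni, block = 1:(nb - 1), participant = 1:np)
  times <- seq(0, 1100, by = 100)
  # half the items per participant are regulated: they intrude now but
  # never again; the rest keep intruding (stable)
  regulated <- meta$item <= ni / 2
  st <- data.frame(participant = meta$participant, item = meta$item,
                   block = meta$block,
                   state = ifelse(regulated, "regulated_intrusive",
                                  "stable_intrusive"))
  base <- 0.4 + 0.05 * rnorm(nrow(meta))
  Y <- matrix(rep(base, length(times)), ncol = length(times))
  late <- times >= 600
  Y[regulated, late] <- Y[regulated, late] * 0.5
  Y <- Y + matrix(rnorm(length(Y), sd = 0.05), nrow = nrow(Y))
  res <- suppressMessages(
    state_contrast(Y, meta, st, contrast = "intrusive", times = times,
                   window = c(0, 1100), n_perm = 40, seed = 3))
  expect_gte(nrow(res$clusters), 1)
  hit <- res$clusters[which.max(abs(res$clusters$mass)), ]
  expect_gte(res$times[hit$end_index], 600)
  expect_lt(hit$p_value, 0.05)

  # identical strengths across states: no clusters
  Y0 <- matrix(rnorm(length(Y), mean = 0.4, sd = 0.05), nrow = nrow(Y))
  res0 <- suppressMessages(
    state_contrast(Y0, meta, st, contrast = "intrusive", times = times,
                   window = c(0, 1100), n_perm = 40, seed = 4))
  expect_true(nrow(res0$clusters) == 0 || min(res0$clusters$p_value) > 0.05)
})
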