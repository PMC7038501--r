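mk_state <- function(scores, slopes_val = 0, K = 15, margin = 0) {
  cfg <- pipeline_config(adapt_margin = margin, window_len = 15L,
                         calibration_contractions = 20L)
  st <- threshold_state(cfg)
  slopes <- replicate(length(scores),
                      matrix(slopes_val, 4, 5,
                             dimnames = dimnames(st$cort_thr)),
                      simplify = FALSE)
  seed_calibration(st, scores, slopes)
}

test_that("calibration seeding places quantile thresholds", {
  st <- mk_state(rep(0.8, 15))
  expect_equal(st$ms_thr, 0.8)  # degenerate quantile, zero margin
  expect_equal(unique(as.numeric(st$cort_thr)), 0)

  # empirical 5th percentile oracle (type-7 interpolation done by hand):
  # h = 1 + 14 * 0.05 = 1.7 for sorted 0.80..0.94
  scores <- seq(0.80, 0.94, by = 0.01)
  st2 <- mk_state(scores)
  expect_equal(st2$ms_thr, 0.80 + 0.7 * 0.01)

  expect_error(mk_state(rep(0.8, 10)), "at least window_len")
  st3 <- threshold_state(pipeline_config())
  expect_error(seed_calibration(st3, rep(1, 15), list()), "equal length")
  expect_error(compute_alerts(0.5, matrix(0, 4, 5), st3), "not seeded")
})

test_that("threshold adaptation is a monotone rolling-median tracker", {
  st <- mk_state(rep(0.9, 15))
  gs <- matrix(0, 4, 5, dimnames = dimnames(st$cort_thr))
  for (i in 1:10) st <- adapt_thresholds(st, 0.9, gs)
  expect_equal(st$ms_thr, 0.9)  # fixed point under identical input

  # a block of lower scores drags the threshold to the block median
  stream <- c(rep(0.9, 5), rep(0.6, 20))
  st2 <- mk_state(rep(0.9, 15))
  hist <- rep(0.9, 15)
  for (s in stream) {
    st2 <- adapt_thresholds(st2, s, gs)
    hist <- c(hist, s)[-1]
    expect_equal(st2$ms_thr, min(0.9, min_running <- stats::median(hist)),
                 tolerance = 1e-12)
  }
  expect_equal(st2$ms_thr, 0.6)

  # later high scores never raise it back
  for (i in 1:20) st2 <- adapt_thresholds(st2, 0.95, gs)
  expect_equal(st2$ms_thr, 0.6)

  # cortical thresholds move only upward
  st3 <- mk_state(rep(0.9, 15), slopes_val = 0)
  hi <- gs; hi[] <- 0.5
  for (i in 1:20) st3 <- adapt_thresholds(st3, 0.9, hi)
  expect_equal(unique(as.numeric(st3$cort_thr)), 0.5)
  for (i in 1:20) st3 <- adapt_thresholds(st3, 0.9, gs)
  expect_equal(unique(as.numeric(st3$cort_thr)), 0.5)

  # explicit reset follows the candidates down again
  st3 <- adapt_thresholds(st3, 0.9, gs, reset = TRUE)
  expect_equal(unique(as.numeric(st3$cort_thr)), 0)
})

test_that("alerts use strict comparisons against the thresholds", {
  st <- mk_state(rep(0.8, 15))
  gs <- matrix(0, 4, 5, dimnames = dimnames(st$cort_thr))
  expect_equal(compute_alerts(0.8, gs, st)$MA, 0L)   # equality is no alert
  expect_equal(compute_alerts(0.79, gs, st)$MA, 1L)

  gs2 <- gs; gs2[2, 3] <- 0.1
  al <- compute_alerts(0.9, gs2, st)
  expect_equal(sum(al$cort_alerts), 1)
  expect_equal(al$cort_alerts[2, 3], 1L)
  gs3 <- gs  # slope exactly at threshold 0
  expect_equal(sum(compute_alerts(0.9, gs3, st)$cort_alerts), 0)
})

test_that("level-1 needs more than 2 groups in more than 2 bands", {
  all_on <- matrix(1L, 4, 5)
  l1 <- level1_flag(all_on)
  expect_equal(unname(l1$GF), rep(1L, 5))
  expect_equal(l1$F1, 1L)

  two_each <- matrix(0L, 4, 5); two_each[1:2, ] <- 1L
  l2 <- level1_flag(two_each)
  expect_equal(sum(l2$GF), 0)
  expect_equal(l2$F1, 0L)

  three_in_three <- matrix(0L, 4, 5); three_in_three[1:3, 1:3] <- 1L
  expect_equal(level1_flag(three_in_three)$F1, 1L)

  # enumeration oracle over per-band alert counts
  for (i in 1:50) {
    counts <- sample(0:4, 5, replace = TRUE)
    ca <- sapply(counts, function(k) c(rep(1L, k), rep(0L, 4 - k)))
    expect_equal(level1_flag(ca)$F1, as.integer(sum(counts > 2) > 2))
  }
})

test_that("level-2 needs fewer than 2 lateralized bands", {
  expect_equal(level2_flag(rep(1, 5), 0.1)$F2, 1L)
  l <- level2_flag(c(1.5, 1.5, 1, 1, 1), 0.1)
  expect_equal(sum(l$LF), 2)
  expect_equal(l$F2, 0L)
  expect_equal(level2_flag(c(1.1, 1, 1, 1, 1), 0.1)$LF[1], 0L)  # boundary
  expect_equal(level2_flag(c(0.9, 1, 1, 1, 1), 0.1)$LF[1], 0L)
  expect_equal(level2_flag(c(0.85, 1, 1, 1, 1), 0.1)$F2, 1L)    # single flag
})

test_that("final decision is the AND of the three flags", {
  grid <- expand.grid(F1 = 0:1, F2 = 0:1, MA = 0:1)
  for (i in seq_len(nrow(grid))) {
    want <- if (all(grid[i, ] == 1)) "loss_of_balance" else "adl"
    expect_equal(classify(grid$F1[i], grid$F2[i], grid$MA[i]), want)
  }
})

test_that("full network equals brute-force gate evaluation on random configs", {
  st <- mk_state(rep(0.8, 15))
  st$epsilon <- 0.1
  set.seed(123)
  for (i in 1:200) {
    score <- runif(1)
    gs <- matrix(runif(20, -0.2, 0.2), 4, 5, dimnames = dimnames(st$cort_thr))
    ratios <- setNames(exp(rnorm(5, 0, 0.3)), colnames(st$cort_thr))
    got <- logic_network(score, gs, ratios, st)
    ca <- matrix(as.integer(gs > st$cort_thr), 4, 5)
    want <- gate_network_oracle(ca, ratios, as.integer(score < st$ms_thr),
                                st$epsilon)
    expect_equal(got$label, want)
  }
})

test_that("flag logic is monotone in its alert inputs", {
  set.seed(55)
  for (i in 1:100) {
    ca <- matrix(rbinom(20, 1, 0.4), 4, 5)
    f1 <- level1_flag(ca)$F1
    off <- which(ca == 0)
    if (length(off)) {
      ca2 <- ca; ca2[sample(off, 1)] <- 1L
      expect_gte(level1_flag(ca2)$F1, f1)
    }
    ratios <- exp(rnorm(5, 0, 0.3))
    f2 <- level2_flag(ratios, 0.1)$F2
    out_bands <- which(abs(ratios - 1) > 0.1)
    if (length(out_bands)) {
      ratios2 <- ratios; ratios2[sample(out_bands, 1)] <- 1
      expect_gte(level2_flag(ratios2, 0.1)$F2, f2)
    }
  }
})
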