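test_that("generators are deterministic under a fixed seed", {
  spec <- scenario_spec(duration_s = 10, seed = 4)
  expect_identical(generate_gait_emg(spec)$data, generate_gait_emg(spec)$data)
  expect_identical(generate_eeg_background(spec)$data,
                   generate_eeg_background(spec)$data)
  # and the ambient RNG stream is left untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_gait_emg(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("EMG energy is confined to scheduled burst windows", {
  spec <- scenario_spec(duration_s = 20, seed = 6, baseline_noise = 0)
  emg <- generate_gait_emg(spec)
  sched <- gait_schedule(spec)
  half <- 3 * spec$burst_sd_ms / 1000
  for (ch in c("LG_R", "AT_L")) {
    x <- channel_signal(emg, ch)
    mask <- rep(FALSE, length(x))
    for (c_s in sched$center_s[sched$channel == ch]) {
      i0 <- max(1, floor((c_s - half) * 500)); i1 <- min(length(x), ceiling((c_s + half) * 500) + 1)
      mask[i0:i1] <- TRUE
    }
    expect_gte(sum(x[mask]^2) / sum(x^2), 0.95)
  }
})

test_that("gastrocnemius burst counts match cadence", {
  spec <- scenario_spec(duration_s = 60, cadence_hz = 0.9, seed = 8)
  sched <- gait_schedule(spec)
  n_lgr <- sum(sched$channel == "LG_R")
  expect_lte(abs(n_lgr - 54), 1)
  expect_error(scenario_spec(cadence_hz = 0), "cadence")
})

test_that("EEG background has a 1/f-like spectrum and zero mean", {
  spec <- scenario_spec(duration_s = 30, seed = 5)
  eeg <- generate_eeg_background(spec)
  x <- channel_signal(eeg, "Cz")
  ps <- stats::spec.pgram(stats::ts(x, frequency = 500), plot = FALSE,
                          taper = 0)
  # total power per 2.5 Hz-wide band, fitted on the log-log scale
  centers <- seq(5, 40, by = 2.5)
  band_pow <- vapply(centers, function(fc) {
    sum(ps$spec[ps$freq > fc - 1.25 & ps$freq <= fc + 1.25])
  }, numeric(1))
  fit <- stats::lm(log10(band_pow) ~ log10(centers))
  slope <- unname(stats::coef(fit)[2])
  expect_gte(slope, -2); expect_lte(slope, -0.5)

  means <- rowMeans(eeg$data)
  se <- apply(eeg$data, 1, sd) / sqrt(ncol(eeg$data))
  expect_true(all(abs(means) < 3 * se * 50))  # correlated samples: wide bound
  expect_lt(max(abs(means)), 0.05 * max(apply(eeg$data, 1, sd)))
})

test_that("slip injection produces a widespread symmetric cortical response", {
  spec <- scenario_spec(duration_s = 30, seed = 12)
  cfg <- pipeline_config()
  eeg0 <- generate_eeg_background(spec)
  emg0 <- generate_gait_emg(spec)
  mod <- inject_event(eeg0, emg0, spec, "slip", onset_s = 20, side = "R")
  eeg <- notch_power_line(bandpass_eeg(mod$eeg, cfg), cfg)
  emg <- notch_power_line(bandpass_emg(mod$emg, cfg), cfg,
                          causal = cfg$emg_causal)
  ooms <- compute_oom_record(emg, cfg)
  tr <- detect_master_triggers(ooms["LG_L", ], ooms["LG_R", ], cfg)
  mt <- tr$mt_sample[tr$mt_sample / 500 > 20][1]
  expect_lt(mt / 500, 21.2)
  cf <- cortical_features(eeg, mt, cfg)
  n_pos <- colSums(cf$group_slopes > 0.005)
  expect_gte(sum(n_pos >= 3), 3)  # >= 3 groups rising in >= 3 bands
  expect_lt(max(abs(cf$lat_ratios - 1)), 0.5)  # symmetric
  expect_equal(mod$annotation$label, "slip")
})

test_that("lateralized events push ratios away from unity", {
  spec <- scenario_spec(duration_s = 30, seed = 13)
  cfg <- pipeline_config()
  eeg0 <- generate_eeg_background(spec)
  emg0 <- generate_gait_emg(spec)
  mod <- inject_event(eeg0, emg0, spec, "curve", onset_s = 20, side = "L")
  eeg <- notch_power_line(bandpass_eeg(mod$eeg, cfg), cfg)
  emg <- notch_power_line(bandpass_emg(mod$emg, cfg), cfg,
                          causal = cfg$emg_causal)
  ooms <- compute_oom_record(emg, cfg)
  tr <- detect_master_triggers(ooms["LG_L", ], ooms["LG_R", ], cfg)
  mt <- tr$mt_sample[tr$mt_sample / 500 > 20][1]
  cf <- cortical_features(eeg, mt, cfg)
  n_out <- sum(cf$lat_ratios > 1 + cfg$epsilon | cf$lat_ratios < 1 - cfg$epsilon)
  expect_gte(n_out, 2)
})

test_that("uninjected sessions look like background to the feature chain", {
  cfg <- pipeline_config()
  spec <- scenario_spec(duration_s = 16, seed = 14)
  eeg0 <- generate_eeg_background(spec)
  emg0 <- generate_gait_emg(spec)
  mod <- inject_event(eeg0, emg0, spec, "slip", onset_s = 8, side = "R")
  # away from the event the modified EEG is bit-identical to background
  pre <- 1:(500 * 6)
  expect_identical(mod$eeg$data[, pre], eeg0$data[, pre])
  post <- (500 * 11):(500 * 16)
  expect_identical(mod$eeg$data[, post], eeg0$data[, post])
})

test_that("session rendering writes consistent truth and is byte-stable", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  ev <- tibble::tibble(onset_s = c(12, 16), label = "slip",
                       side = c("R", "L"), duration_s = 0.8)
  spec <- scenario_spec(duration_s = 20, events = ev, seed = 3)
  s1 <- generate_session(spec, dir = dir1)
  s2 <- generate_session(spec, dir = dir2)
  expect_equal(sum(s1$truth$label == "slip"), 2)
  expect_true(all(s1$truth$label %in% event_labels()))
  for (f in c("eeg.csv", "emg.csv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  # walk steps cover the gastrocnemius bursts
  expect_gt(sum(s1$truth$label == "walk_step"), 25)

  too_close <- tibble::tibble(onset_s = c(5, 6), label = "slip",
                              side = c("R", "L"), duration_s = 0.8)
  expect_error(scenario_spec(duration_s = 20, events = too_close), "2 s")
  expect_error(scenario_spec(duration_s = 10,
                             events = tibble::tibble(onset_s = 12,
                                                     label = "slip",
                                                     side = "R",
                                                     duration_s = 0.8)),
               "inside")
})
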