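test_that("pre-trigger window takes exactly the 400 samples before the edge", {
  cfg <- pipeline_config()
  eeg <- mc_record(matrix(rep(1:500, each = 13), 13, byrow = FALSE),
                   channel_map()$eeg_channels, fs = 500)
  eeg$data[] <- rep(1:500, each = 13)
  w <- extract_pretrigger_window(eeg, 401, cfg)
  expect_equal(dim(w), c(13, 400))
  expect_equal(w[1, ], eeg$data[1, 1:400])
  expect_error(extract_pretrigger_window(eeg, 400, cfg), "history")
  const <- mc_record(matrix(2, 13, 500), channel_map()$eeg_channels, 500)
  expect_true(all(extract_pretrigger_window(const, 450, cfg) == 2))
})

test_that("artifact attenuation is identity by default and clips spikes", {
  cfg <- pipeline_config()
  set.seed(3)
  w <- matrix(rnorm(13 * 400), 13)
  expect_identical(attenuate_artifacts(w, cfg), w)

  wcfg <- pipeline_config(artifact_mode = "winsorize", winsor_k = 5)
  ref_sd <- rep(1, 13)
  clean <- attenuate_artifacts(w, wcfg, ref_sd = ref_sd)
  expect_equal(clean, w)  # nothing beyond 5 SD in a small normal sample

  spiked <- w
  spiked[4, 100] <- 10
  out <- attenuate_artifacts(spiked, wcfg, ref_sd = ref_sd)
  expect_equal(out[4, 100], 5)  # clipped to winsor_k * SD
  expect_equal(out[-4, ], spiked[-4, ])

  # user-supplied cleaner plugs in
  expect_equal(attenuate_artifacts(w, cfg, cleaner = function(x) x * 0),
               w * 0)
})

test_that("sliding FFT windows tile the buffer and conserve energy", {
  cfg <- pipeline_config()
  zero <- matrix(0, 13, 400)
  sp <- sliding_fft(zero, cfg)
  expect_equal(dim(sp$power), c(13, 101, 20))
  expect_equal(max(abs(sp$power)), 0)
  expect_equal(sp$offsets, seq(0, 190, by = 10))
  expect_lte(max(sp$offsets) + cfg$L_win, 400)
  expect_equal(sp$freq_hz[2] - sp$freq_hz[1], 2.5)

  # a unit 10 Hz tone concentrates in its own bin in every window
  tt <- (0:399) / 500
  tone <- matrix(rep(sin(2 * pi * 10 * tt), 13), 13, byrow = TRUE)
  sp2 <- sliding_fft(tone, cfg)
  bin10 <- which(sp2$freq_hz == 10)
  for (wdx in c(1, 10, 20)) {
    expect_gt(sp2$power[1, bin10, wdx] / sum(sp2$power[1, , wdx]), 0.9)
  }

  # Parseval: one-sided bin powers sum to the segment mean square
  set.seed(8)
  rnd <- matrix(rnorm(13 * 400), 13)
  sp3 <- sliding_fft(rnd, cfg)
  for (wdx in c(1, 7, 20)) {
    seg <- rnd[, (sp3$offsets[wdx] + 1):(sp3$offsets[wdx] + 200)]
    expect_equal(apply(sp3$power[, , wdx], 1, sum), rowMeans(seg^2),
                 tolerance = 1e-6)
  }

  # inconsistent window arithmetic is rejected when the config is built
  expect_error(pipeline_config(step = 12), "pre-trigger")
})

test_that("band-to-bin mapping follows the stated ranges with half-bin slack", {
  cfg <- pipeline_config()
  freq <- seq(0, 250, by = 2.5)
  bins <- band_bin_indices(freq, cfg)
  expect_equal(freq[bins$theta], c(5, 7.5))
  expect_equal(freq[bins$alpha], c(7.5, 10, 12.5))
  expect_equal(freq[bins$beta1], c(12.5, 15))
  expect_equal(freq[bins$beta2], c(15, 17.5, 20))
  expect_equal(freq[bins$beta3], seq(20, 40, by = 2.5))

  # explicit bin lists override the rule
  cfg2 <- pipeline_config(band_bins = list(theta = 5))
  expect_equal(freq[band_bin_indices(freq, cfg2)$theta], 5)

  cfg3 <- pipeline_config(bands = list(theta = c(0.2, 0.8)))
  expect_error(band_bin_indices(freq, cfg3), "no FFT bins")
})

test_that("band multiplexing sums per-bin dB with a finite floor", {
  cfg <- pipeline_config()
  zero <- matrix(0, 13, 400)
  tens <- band_multiplex(sliding_fft(zero, cfg), cfg)
  bins <- band_bin_indices(seq(0, 250, 2.5), cfg)
  floor_db <- 10 * log10(cfg$db_floor)
  for (b in names(bins)) {
    expect_equal(unique(as.numeric(tens[, b, ])),
                 length(bins[[b]]) * floor_db)
  }

  # a tone in the alpha band lifts alpha above its floor, leaves theta there
  tt <- (0:399) / 500
  tone <- matrix(rep(sin(2 * pi * 10 * tt), 13), 13, byrow = TRUE)
  tens2 <- band_multiplex(sliding_fft(tone, cfg), cfg)
  expect_gt(tens2[1, "alpha", 1], length(bins$alpha) * floor_db)

  # doubling all powers adds 10*log10(2) dB per bin in the band
  set.seed(1)
  rnd <- matrix(rnorm(13 * 400), 13)
  sp <- sliding_fft(rnd, cfg)
  sp2 <- sp; sp2$power <- 2 * sp$power
  d <- band_multiplex(sp2, cfg) - band_multiplex(sp, cfg)
  for (b in names(bins)) {
    expect_equal(unique(round(as.numeric(d[, b, ]), 9)),
                 round(length(bins[[b]]) * 10 * log10(2), 9))
  }
})

test_that("slope estimation matches closed-form and generic least squares", {
  cfg <- pipeline_config()
  t_ms <- fit_times_ms(cfg)
  expect_equal(t_ms, seq(20, 400, by = 20))

  const <- array(7, dim = c(13, 5, 20))
  sl <- estimate_slopes(const, cfg)
  expect_equal(max(abs(sl$m_hat)), 0)
  expect_equal(unique(as.numeric(sl$q_hat)), 7)

  line <- array(rep(2 * t_ms + 1, each = 65), dim = c(13, 5, 20))
  sl2 <- estimate_slopes(line, cfg)
  expect_equal(as.numeric(sl2$m_hat), rep(2, 65), tolerance = 1e-9)
  expect_equal(as.numeric(sl2$q_hat), rep(1, 65), tolerance = 1e-9)

  set.seed(21)
  rnd <- array(rnorm(13 * 5 * 20), dim = c(13, 5, 20))
  sl3 <- estimate_slopes(rnd, cfg)
  for (ch in c(1, 13)) for (b in 1:5) {
    fit <- stats::lm.fit(cbind(1, t_ms), rnd[ch, b, ])
    expect_equal(sl3$q_hat[ch, b], unname(fit$coefficients[1]),
                 tolerance = 1e-9)
    expect_equal(sl3$m_hat[ch, b], unname(fit$coefficients[2]),
                 tolerance = 1e-9)
  }

  expect_error(estimate_slopes(array(0, dim = c(13, 5, 1)), cfg), "two windows")
})

test_that("slope estimator is unbiased under additive noise", {
  cfg <- pipeline_config()
  t_ms <- fit_times_ms(cfg)
  set.seed(77)
  n_rep <- 1000
  m_hats <- replicate(n_rep, {
    y <- array(rep(t_ms, each = 1), dim = c(1, 1, 20)) + rnorm(20)
    estimate_slopes(y, cfg)$m_hat[1, 1]
  })
  se <- sd(m_hats) / sqrt(n_rep)
  expect_lt(abs(mean(m_hats) - 1), 3 * se)
})

test_that("generalization sums each functional group's own channels", {
  m <- matrix(0, 13, 5, dimnames = list(channel_map()$eeg_channels,
                                        names(pipeline_config()$bands)))
  expect_equal(max(abs(generalize(m))), 0)

  m["F3", "alpha"] <- 1; m["Fz", "alpha"] <- 2; m["F4", "alpha"] <- 3
  g <- generalize(m)
  expect_equal(g["SMA", "alpha"], 6)
  expect_equal(g["M1", "alpha"], 0)

  # S1 is symmetric in its four channels
  set.seed(2)
  m2 <- m; m2[c("Cp5", "Cp1", "Cp2", "Cp6"), ] <- rnorm(20)
  m3 <- m2; m3[c("Cp1", "Cp6", "Cp5", "Cp2"), ] <- m2[c("Cp5", "Cp1", "Cp2", "Cp6"), ]
  expect_equal(generalize(m2)["S1", ], generalize(m3)["S1", ])
})

test_that("lateralization ratios compare hemisphere sums with a floor", {
  cfg <- pipeline_config()
  m <- matrix(0.5, 13, 5, dimnames = list(channel_map()$eeg_channels,
                                          names(cfg$bands)))
  expect_equal(unname(lateralize(m, cfg)), rep(1, 5))

  m2 <- m
  m2[c("F3", "C3", "P3", "Cp1", "Cp5"), ] <-
    2 * m2[c("F4", "C4", "P4", "Cp2", "Cp6"), ]
  expect_equal(unname(lateralize(m2, cfg)), rep(2, 5))

  m3 <- m; m3[] <- -1
  expect_equal(unname(lateralize(m3, cfg)), rep(1, 5))  # both sides floored
})

test_that("ramped-variance windows yield positive slopes, stationary near zero", {
  cfg <- pipeline_config()
  set.seed(31)
  ramp_env <- seq(0.2, 3, length.out = 400)
  wr <- matrix(rnorm(13 * 400), 13,
               dimnames = list(channel_map()$eeg_channels, NULL)) *
    rep(ramp_env, each = 13)
  sl_r <- generalize(estimate_slopes(band_multiplex(sliding_fft(wr, cfg), cfg),
                                     cfg))
  expect_true(all(sl_r > 0))

  stat_means <- replicate(8, {
    ws <- matrix(rnorm(13 * 400), 13,
                 dimnames = list(channel_map()$eeg_channels, NULL))
    mean(generalize(estimate_slopes(
      band_multiplex(sliding_fft(ws, cfg), cfg), cfg)))
  })
  expect_lt(abs(mean(stat_means)), 0.05)
})
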