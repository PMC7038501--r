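# shared fixtures, built in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

sinusoid_record <- function(freq_hz, fs = 500, n = 5000, channels = "ch1",
                            amp = 1) {
  tt <- (seq_len(n) - 1) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq_hz * tt), length(channels)),
                 nrow = length(channels), byrow = TRUE)
  mc_record(data, channels, fs = fs)
}

# steady-state RMS gain of a filtered single-channel record vs its input
rms_gain <- function(out_rec, in_rec, trim = 1000) {
  n <- n_samples(in_rec)
  idx <- trim:(n - trim)
  stats::sd(out_rec$data[1, idx]) / stats::sd(in_rec$data[1, idx])
}

slip_session <- function(seed, duration_s = 70) {
  ev <- tibble::tibble(onset_s = seq(25, 61, by = 4), label = "slip",
                       side = rep(c("R", "L"), 5), duration_s = 0.8)
  generate_session(scenario_spec(duration_s = duration_s, events = ev,
                                 seed = seed))
}

adl_session <- function(seed, duration_s = 70) {
  ev <- tibble::tibble(
    onset_s = seq(25, 61, by = 4),
    label = rep(c("curve", "obstacle", "tug_sit", "tug_stand", "curve"),
                each = 2),
    side = rep(c("R", "L"), 5), duration_s = 0.8)
  generate_session(scenario_spec(duration_s = duration_s, events = ev,
                                 seed = seed))
}

# brute-force per-sample ON/OFF recomputation (independent of the
# cumulative-sum implementation)
naive_oom <- function(x, M = 250, N = 125, floor = 1e-12) {
  n <- length(x)
  out <- integer(n)
  for (t in M:n) {
    pm <- mean(x[(t - M + 1):t]^2)
    pn <- mean(x[(t - N + 1):t]^2)
    out[t] <- as.integer(pn > pm && pn > floor)
  }
  out
}

# independent symbolic evaluation of the three-level gate network
gate_network_oracle <- function(cort_alerts, lat_ratios, ma, epsilon) {
  gf <- apply(cort_alerts, 2, function(col) sum(col) > 2)
  f1 <- sum(gf) > 2
  lf <- abs(lat_ratios - 1) > epsilon
  f2 <- sum(lf) < 2
  if (f1 && f2 && ma == 1) "loss_of_balance" else "adl"
}
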