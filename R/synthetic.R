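#' Scenario specification for synthetic sessions
#'
#' Describes a gait-locked EEG+EMG session: duration, cadence, the event
#' schedule and signal/noise amplitudes. A fixed `seed` makes the rendered
#' session fully deterministic.
#'
#' The default amplitudes emulate the signal structure the detector
#' assumes: per-muscle EMG bursts locked to gait phase (the lateral
#' gastrocnemius at midstance, so master triggers arise naturally, with the
#' contralateral anterior tibialis and biceps femoris co-active slightly
#' ahead of it), an EEG background of stationary narrowband rhythms with a
#' 1/f power profile over a pink-noise floor, a widespread symmetric EEG
#' power ramp plus a muscular co-contraction anomaly for slips, and a
#' lateralized EEG ramp with an unchanged muscular pattern for daily-life
#' events.
#'
#' @param duration_s session length in seconds.
#' @param cadence_hz gait cycles per second per leg.
#' @param events data frame with `onset_s`, `label`, `side` rows (may be
#'   `NULL` for plain walking).
#' @param seed integer RNG seed.
#' @param burst_amp EMG burst amplitude (arbitrary units).
#' @param baseline_noise EMG baseline noise SD relative to `burst_amp`
#'   (0 keeps inter-burst samples silent; the ON/OFF rule is a relative
#'   power comparison, so stationary baseline noise produces spurious
#'   activation flickers at any amplitude).
#' @param burst_sd_ms Gaussian burst envelope SD, ms (support +-3 SD).
#' @param jitter_sd_ms per-burst timing jitter SD, ms.
#' @param eeg_amp EEG background scale (arbitrary units).
#' @param osc_amp amplitude scale of the bank of ongoing narrowband rhythms
#'   spanning 4-40 Hz (one oscillator per 2.5 Hz analysis bin, amplitudes
#'   decaying as `f^-0.5` so power follows 1/f), relative to `eeg_amp`.
#' @param noise_amp amplitude of the broadband pink-noise floor relative to
#'   `eeg_amp`.
#' @param slip_gain peak multiplicative EEG amplitude gain of a slip ramp
#'   (applied to all channels).
#' @param adl_gain peak gain of a lateralized daily-life ramp (one
#'   hemisphere only).
#' @param fs sampling rate, Hz.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(duration_s = 60, cadence_hz = 0.9, events = NULL,
                          seed = 1L, burst_amp = 1, baseline_noise = 0,
                          burst_sd_ms = 50, jitter_sd_ms = 20,
                          eeg_amp = 1, osc_amp = 1, noise_amp = 0.05,
                          slip_gain = 4, adl_gain = 2, fs = 500) {
  if (cadence_hz <= 0) stop("cadence_hz must be > 0.", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0.", call. = FALSE)
  if (!is.null(events)) {
    events <- validate_annotations(
      tibble::tibble(onset_s = events$onset_s,
                     duration_s = events$duration_s %||% 0.8,
                     label = events$label, side = events$side)
    )
    if (any(events$onset_s >= duration_s)) {
      stop("All events must start inside the session.", call. = FALSE)
    }
    if (nrow(events) > 1 && any(diff(sort(events$onset_s)) < 2)) {
      stop("Events closer than 2 s would overlap; space them out.",
           call. = FALSE)
    }
  }
  structure(
    list(duration_s = duration_s, cadence_hz = cadence_hz, events = events,
         seed = as.integer(seed), burst_amp = burst_amp,
         baseline_noise = baseline_noise, burst_sd_ms = burst_sd_ms,
         jitter_sd_ms = jitter_sd_ms, eeg_amp = eeg_amp,
         osc_amp = osc_amp, noise_amp = noise_amp,
         slip_gain = slip_gain, adl_gain = adl_gain, fs = fs),
    class = "scenario_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-leg burst phases (fraction of that leg's gait cycle); the left leg is
# offset half a cycle. The 0.83-phase AT/BF bursts of the swing leg lead the
# stance leg's LG midstance burst by 0.07 cycle (~80 ms at 0.9 Hz), so they
# are reliably ON when the gastrocnemius edge fires; the stance leg's own
# loading-response VM/RF activity is still decaying through that edge. The
# five of them form the "standard" pattern the weights learn. Burst phases
# keep every other activation tail clear of the gastrocnemius edges, so
# pattern membership is stable from step to step.
muscle_phases <- function() {
  list(AT = c(0.60, 0.83), VM = 0.10, RF = 0.15, LG = 0.40, BF = 0.83)
}

#' Deterministic gait burst schedule for a scenario
#'
#' One row per EMG burst: muscle, side, ideal phase, jittered center time.
#' The jitter stream is drawn from a seed derived from `spec$seed` only, so
#' the schedule is identical for every consumer of the same spec (the
#' generator and the event injector must agree on burst positions).
#'
#' @param spec a [scenario_spec()].
#' @return Tibble with `muscle`, `side`, `channel`, `phase`, `center_s`.
#' @export
gait_schedule <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  T_cycle <- 1 / spec$cadence_hz
  phases <- muscle_phases()
  rows <- list()
  for (m in names(phases)) {
    for (side in c("R", "L")) {
      off <- if (side == "L") 0.5 else 0
      for (ph in phases[[m]]) {
        centers <- seq((ph + off) * T_cycle, spec$duration_s, by = T_cycle)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          muscle = m, side = side, channel = paste0(m, "_", side),
          phase = ph, center_s = centers)
      }
    }
  }
  sched <- dplyr::arrange(dplyr::bind_rows(rows), center_s)
  withr_seed <- spec$seed %% 100000L * 17L + 3L
  old <- .Random.seed_get()
  set.seed(withr_seed)
  sched$center_s <- sched$center_s +
    stats::rnorm(nrow(sched), 0, spec$jitter_sd_ms / 1000)
  .Random.seed_set(old)
  # keep bursts whose support lies inside the recording
  half <- 3 * spec$burst_sd_ms / 1000
  dplyr::filter(sched, .data$center_s - half > 0,
                .data$center_s + half < spec$duration_s)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

gaussian_burst <- function(n, center_s, sd_s, fs) {
  half <- 3 * sd_s
  i0 <- max(1L, floor((center_s - half) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + half) * fs) + 1L)
  if (i0 > i1) return(NULL)
  tt <- ((i0:i1) - 1) / fs
  list(idx = i0:i1, env = exp(-(tt - center_s)^2 / (2 * sd_s^2)))
}

#' Generate gait-phase-locked EMG
#'
#' Ten channels at `fs` Hz. Each scheduled burst is a Gaussian envelope
#' (SD `burst_sd_ms`, support +-3 SD) modulating white noise, band-limited
#' downstream by the standard EMG preprocessing; optional stationary
#' baseline noise is added on top. Deterministic per seed.
#'
#' @param spec a [scenario_spec()].
#' @param schedule optional precomputed [gait_schedule()] (e.g. with event
#'   modifications); defaults to the spec's own schedule.
#' @return An [mc_record()] with the 10 muscles of [channel_map()].
#' @export
generate_gait_emg <- function(spec, schedule = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  map <- channel_map()
  n <- round(spec$duration_s * spec$fs)
  sched <- schedule %||% gait_schedule(spec)
  old <- .Random.seed_get()
  set.seed(spec$seed)
  data <- matrix(0, length(map$emg_muscles), n,
                 dimnames = list(map$emg_muscles, NULL))
  for (k in seq_len(nrow(sched))) {
    b <- gaussian_burst(n, sched$center_s[k], spec$burst_sd_ms / 1000, spec$fs)
    if (is.null(b)) next
    amp <- spec$burst_amp *
      (if ("amp" %in% names(sched)) sched$amp[k] else 1)
    data[sched$channel[k], b$idx] <- data[sched$channel[k], b$idx] +
      amp * b$env * stats::rnorm(length(b$idx))
  }
  if (spec$baseline_noise > 0) {
    data <- data + spec$baseline_noise * spec$burst_amp *
      matrix(stats::rnorm(length(data)), nrow(data))
  }
  .Random.seed_set(old)
  mc_record(data, map$emg_muscles, fs = spec$fs)
}

#' Generate stationary EEG background
#'
#' Thirteen channels of ongoing narrowband rhythms plus a pink-noise floor.
#' One oscillator sits at every 2.5 Hz analysis bin from 5 to 40 Hz with a
#' per-channel random phase; amplitudes decay as `f^-0.5`, so the overall
#' power spectrum keeps the 1/f shape of resting EEG (log-log slope near -1
#' over 2-40 Hz). Stationary rhythms in every band of interest are the
#' "standard gait" structure the detector's calibration assumes: band
#' powers are stable between contractions, and event-related power ramps
#' stand out against them. Deterministic per seed.
#'
#' @param spec a [scenario_spec()].
#' @return An [mc_record()] with the 13 sites of [channel_map()].
#' @export
generate_eeg_background <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  map <- channel_map()
  n <- round(spec$duration_s * spec$fs)
  old <- .Random.seed_get()
  set.seed(spec$seed + 104729L)  # distinct stream from the EMG draw
  tt <- (seq_len(n) - 1) / spec$fs
  freqs <- c(0, seq_len(n - 1)) * spec$fs / n
  shape <- c(0, 1 / sqrt(pmax(freqs[-1], 1)))  # amplitude ~ f^-1/2, power ~ 1/f
  osc_f <- seq(5, 40, by = 2.5)                # one rhythm per analysis bin
  osc_a <- spec$osc_amp / sqrt(osc_f / 10)     # power ~ 1/f, unit scale at 10 Hz
  data <- matrix(0, 13, n, dimnames = list(map$eeg_channels, NULL))
  for (i in 1:13) {
    white <- stats::rnorm(n)
    pink <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
    pink <- pink / stats::sd(pink)
    phases <- stats::runif(length(osc_f), 0, 2 * pi)
    osc <- colSums(osc_a * sin(outer(2 * pi * osc_f, tt) + phases))
    data[i, ] <- spec$eeg_amp * (spec$noise_amp * pink + osc)
  }
  .Random.seed_set(old)
  mc_record(data, map$eeg_channels, fs = spec$fs)
}

#' Event templates
#'
#' Signal signatures per event label. A slip combines a widespread,
#' left/right-symmetric EEG power ramp over the ~800 ms preceding the
#' triggering gastrocnemius burst with a muscular co-contraction anomaly
#' (the standard swing-leg companions are suppressed and agonist/antagonist
#' bursts are added bilaterally). Daily-life events (curve, TUG
#' transitions, obstacle) keep the standard muscular pattern and apply the
#' EEG ramp to one hemisphere only, lateralized toward the movement side.
#'
#' @return Named list of template descriptions.
#' @export
event_templates <- function() {
  lat_left <- c("F3", "C3", "P3", "Cp1", "Cp5")
  lat_right <- c("F4", "C4", "P4", "Cp2", "Cp6")
  list(
    slip = list(eeg_channels = "all", symmetric = TRUE, emg_anomaly = TRUE),
    curve = list(lateralized = TRUE, emg_anomaly = FALSE),
    tug_sit = list(lateralized = TRUE, emg_anomaly = FALSE),
    tug_stand = list(lateralized = TRUE, emg_anomaly = FALSE),
    obstacle = list(lateralized = TRUE, emg_anomaly = FALSE),
    .sides = list(L = lat_left, R = lat_right)
  )
}

# linear gain profile rising from 1 to `gain` over [t0, t1], holding briefly,
# then returning to 1
ramp_gain <- function(n, fs, t0, t1, hold_s, gain) {
  tt <- (seq_len(n) - 1) / fs
  g <- rep(1, n)
  rise <- tt >= t0 & tt <= t1
  g[rise] <- 1 + (gain - 1) * (tt[rise] - t0) / (t1 - t0)
  hold <- tt > t1 & tt <= t1 + hold_s
  g[hold] <- gain
  fall <- tt > t1 + hold_s & tt <= t1 + hold_s + 0.2
  g[fall] <- gain + (1 - gain) * (tt[fall] - t1 - hold_s) / 0.2
  g
}

#' Inject an event into a rendered session
#'
#' Modifies the EEG (and, for slips, the EMG burst structure) around the
#' first master-trigger-generating gastrocnemius burst following the event
#' onset, per the label's [event_templates()] entry, and returns the
#' matching annotation row.
#'
#' @param eeg,emg [mc_record()]s from the generators.
#' @param spec the [scenario_spec()] that produced them (burst positions
#'   are recomputed from it).
#' @param label event label (no `walk_step`).
#' @param onset_s event onset in seconds.
#' @param side `"L"` or `"R"`.
#' @return List with modified `eeg`, `emg` and an `annotation` tibble row.
#' @export
inject_event <- function(eeg, emg, spec, label, onset_s, side = "R") {
  stopifnot(inherits(spec, "scenario_spec"))
  tmpl <- event_templates()[[label]]
  if (is.null(tmpl)) stop("No template for label '", label, "'.", call. = FALSE)
  sched <- gait_schedule(spec)
  sd_pre <- 3 * spec$burst_sd_ms / 1000
  # bind to the first LG burst whose ON edge (~support start) follows the
  # onset, so the detection can never precede the perturbation
  lg <- dplyr::filter(sched, .data$muscle == "LG",
                      .data$center_s - sd_pre > onset_s + 0.02)
  if (!nrow(lg)) stop("No gastrocnemius burst after onset ", onset_s, " s.",
                      call. = FALSE)
  lg <- lg[which.min(lg$center_s), ]
  sd_s <- spec$burst_sd_ms / 1000
  mt_pred <- lg$center_s - 3 * sd_s   # approximate ON-edge time
  n <- n_samples(eeg)

  gain <- if (label == "slip") spec$slip_gain else spec$adl_gain
  g <- ramp_gain(n, spec$fs, mt_pred - 0.85, mt_pred + 0.06, 0.05, gain)
  chans <- if (isTRUE(tmpl$symmetric) || identical(tmpl$eeg_channels, "all")) {
    eeg$channel_names
  } else {
    event_templates()$.sides[[side]]
  }
  eeg$data[chans, ] <- sweep(eeg$data[chans, , drop = FALSE], 2, g, `*`)

  if (isTRUE(tmpl$emg_anomaly)) {
    other <- if (lg$side == "R") "L" else "R"
    # suppress the bursts that normally accompany this trigger — the
    # contralateral swing companions and the stance leg's loading response —
    # breaking the learned pattern
    comp <- dplyr::filter(
      sched,
      (.data$muscle %in% c("AT", "BF") & .data$side == other &
         abs(.data$center_s - mt_pred) < 0.25) |
        (.data$muscle %in% c("VM", "RF") & .data$side == lg$side &
           .data$center_s > mt_pred - 0.45 & .data$center_s < mt_pred + 0.1))
    for (k in seq_len(nrow(comp))) {
      b <- gaussian_burst(n, comp$center_s[k], sd_s, spec$fs)
      if (!is.null(b)) emg$data[comp$channel[k], b$idx] <- 0
    }
    # the reactive agonist/antagonist co-contraction follows the trigger
    # (ankle-strategy response latency), on the stance side plus both vasti
    old <- .Random.seed_get()
    set.seed(spec$seed + round(onset_s * 1000) %% 100000L)
    cc <- c(paste0(c("AT", "BF"), "_", lg$side), "VM_L", "VM_R")
    for (ch in cc) {
      b <- gaussian_burst(n, mt_pred + 0.2, sd_s, spec$fs)
      if (!is.null(b)) {
        emg$data[ch, b$idx] <- emg$data[ch, b$idx] +
          spec$burst_amp * b$env * stats::rnorm(length(b$idx))
      }
    }
    .Random.seed_set(old)
  }
  list(eeg = eeg, emg = emg,
       annotation = tibble::tibble(onset_s = onset_s, duration_s = 0.8,
                                   label = label, side = side))
}

#' Render a full synthetic session
#'
#' Generates the EEG background and gait EMG, injects every scheduled
#' event, and builds the ground-truth table (one `walk_step` row per
#' gastrocnemius burst not tied to an event, plus one row per event).
#' Optionally writes the three files plus a session manifest.
#'
#' @param spec a [scenario_spec()].
#' @param dir if non-`NULL`, directory to write `eeg.csv`, `emg.csv`,
#'   `truth.tsv` and `session.yaml` into.
#' @param format signal file format (`"csv"`, `"tsv"` or `"edf"`).
#' @return List with `eeg`, `emg` records, `truth` tibble and (if written)
#'   `paths`.
#' @export
generate_session <- function(spec, dir = NULL, format = "csv") {
  stopifnot(inherits(spec, "scenario_spec"))
  eeg <- generate_eeg_background(spec)
  emg <- generate_gait_emg(spec)
  truth_events <- list()
  if (!is.null(spec$events) && nrow(spec$events)) {
    ev <- dplyr::arrange(spec$events, .data$onset_s)
    for (k in seq_len(nrow(ev))) {
      mod <- inject_event(eeg, emg, spec, ev$label[k], ev$onset_s[k],
                          ev$side[k])
      eeg <- mod$eeg; emg <- mod$emg
      truth_events[[k]] <- mod$annotation
    }
  }
  sched <- gait_schedule(spec)
  lg <- dplyr::filter(sched, .data$muscle == "LG")
  steps <- tibble::tibble(
    onset_s = lg$center_s - 3 * spec$burst_sd_ms / 1000,
    duration_s = 6 * spec$burst_sd_ms / 1000,
    label = "walk_step", side = lg$side
  )
  truth <- dplyr::bind_rows(c(truth_events, list(steps)))
  truth <- dplyr::arrange(truth, .data$onset_s)
  out <- list(eeg = eeg, emg = emg, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (format == "edf") "edf" else format
    paths <- list(eeg = file.path(dir, paste0("eeg.", ext)),
                  emg = file.path(dir, paste0("emg.", ext)),
                  truth = file.path(dir, "truth.tsv"),
                  manifest = file.path(dir, "session.yaml"))
    write_signals(eeg, paths$eeg, format = if (format == "edf") "edf" else format)
    write_signals(emg, paths$emg, format = if (format == "edf") "edf" else format)
    write_annotations(truth, paths$truth)
    yaml::write_yaml(list(eeg = basename(paths$eeg), emg = basename(paths$emg),
                          truth = basename(paths$truth), seed = spec$seed),
                     paths$manifest)
    out$paths <- paths
  }
  out
}
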