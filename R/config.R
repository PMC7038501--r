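#' Pipeline configuration
#'
#' Collects every tunable of the detection chain with its default. Defaults
#' reproduce the reference operating point: a 250/125-sample moving power
#' threshold on 500 Hz EMG, an 11-sample muscular-pattern window around each
#' master trigger, a 400-sample (800 ms) pre-trigger EEG buffer analyzed with
#' a 200-sample sliding FFT (20 windows, 10-sample step, 2.5 Hz resolution),
#' five bands of interest, and a 15-contraction adaptive threshold window.
#'
#' @param M long EMG power window, samples (moving threshold).
#' @param N short EMG power window, samples (instantaneous power); `M > N >= 1`.
#' @param refractory_ms minimum spacing between accepted master triggers.
#' @param power_floor absolute mean-square power below which a sample is
#'   never ON, regardless of the window comparison; a numerical guard far
#'   below any physiologic EMG power.
#' @param Lw muscular-pattern window length in samples, odd (centered on the
#'   trigger edge: (Lw-1)/2 before and after).
#' @param pretrigger_samples EEG history analyzed before each trigger.
#' @param L_win sliding-FFT window length, samples.
#' @param step sliding-FFT hop, samples.
#' @param nW number of sliding-FFT windows per contraction.
#' @param bands named list of `c(low, high)` band edges in Hz.
#' @param band_bins optional named list of explicit bin center frequencies
#'   (Hz) per band, overriding the edge-based mapping.
#' @param db_floor power floor applied before dB conversion.
#' @param db_sum if `TRUE` (default) band values are sums of per-bin dB
#'   powers; if `FALSE`, raw powers are summed and converted once.
#' @param lat_floor rectification floor applied to each hemisphere sum before
#'   the lateralization ratio.
#' @param epsilon lateralization tolerance: ratios outside `1 +/- epsilon`
#'   raise a lateralization flag. The slope ratio of two hemisphere sums
#'   carries multiplicative dispersion of a few tens of percent even for a
#'   strong, perfectly symmetric power build-up (periodogram variance plus
#'   modulation leakage between neighboring bins), while genuinely
#'   lateralized responses push the ratio beyond 2 or collapse it toward
#'   the rectification floor, so the default tolerance is wide.
#' @param window_len adaptive-threshold observation window, contractions.
#' @param calib_quantile q for threshold seeding: muscular threshold at the
#'   q-quantile of calibration scores, cortical thresholds at 1 - q.
#' @param calibration_contractions contractions consumed to seed weights and
#'   thresholds before decisions are emitted.
#' @param adapt_margin additive safety margin (score units) between the
#'   muscular threshold statistic (seeding quantile or rolling median) and
#'   the operative threshold, which sits `adapt_margin` below it. A nonzero
#'   margin keeps a degenerate calibration distribution (every standard
#'   contraction scoring exactly alike) from placing the threshold on top
#'   of the standard value itself.
#' @param cort_margin additive safety margin (dB/ms) added above each
#'   cortical threshold statistic; 0 by default since the slope
#'   distribution is continuous and its upper quantile is already a bound.
#' @param weight_mode `"exponential"` or `"batch_recount"` weight updates.
#' @param weight_lambda learning rate for exponential weight updates.
#' @param eeg_band,emg_band,notch_band filter edges in Hz.
#' @param eeg_order,emg_order,notch_order Butterworth orders (overall order
#'   of the band filter; doubled again by zero-phase application).
#' @param eeg_causal,emg_causal if `TRUE` the corresponding filter chain
#'   runs causally (single pass) instead of zero-phase forward-backward.
#'   EEG defaults to zero-phase (offline analysis, no group-delay skew of
#'   the pre-trigger window); EMG defaults to causal, mirroring the on-node
#'   filter chain: a zero-phase IIR pre-rings ahead of each burst, and the
#'   scale-free ON/OFF power rule would latch onto that anticipatory energy
#'   and fire activations before the physical contraction.
#' @param artifact_mode `"identity"` or `"winsorize"` pre-trigger EEG cleaning.
#' @param winsor_k clip level in calibration-SD multiples for winsorize mode.
#' @param match_window_s max truth-to-detection latency counted as a hit.
#' @param fs operating sampling rate, Hz.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(M = 250L, N = 125L, refractory_ms = 300,
                            power_floor = 1e-12,
                            Lw = 11L, pretrigger_samples = 400L,
                            L_win = 200L, step = 10L, nW = 20L,
                            bands = list(theta = c(4, 7), alpha = c(8, 12),
                                         beta1 = c(13, 15), beta2 = c(16, 20),
                                         beta3 = c(21, 40)),
                            band_bins = NULL,
                            db_floor = 1e-12, db_sum = TRUE,
                            lat_floor = 1e-6, epsilon = 0.5,
                            window_len = 15L, calib_quantile = 0.05,
                            calibration_contractions = 20L,
                            adapt_margin = 0.1, cort_margin = 0,
                            weight_mode = c("exponential", "batch_recount"),
                            weight_lambda = 1 / 15,
                            eeg_band = c(1, 40), emg_band = c(15, 250),
                            notch_band = c(48, 52),
                            eeg_order = 8L, emg_order = 8L, notch_order = 4L,
                            eeg_causal = FALSE, emg_causal = TRUE,
                            artifact_mode = c("identity", "winsorize"),
                            winsor_k = 5,
                            match_window_s = 1.0,
                            fs = 500) {
  weight_mode <- match.arg(weight_mode)
  artifact_mode <- match.arg(artifact_mode)
  cfg <- list(
    M = as.integer(M), N = as.integer(N), refractory_ms = refractory_ms,
    power_floor = power_floor,
    Lw = as.integer(Lw), pretrigger_samples = as.integer(pretrigger_samples),
    L_win = as.integer(L_win), step = as.integer(step), nW = as.integer(nW),
    bands = bands, band_bins = band_bins,
    db_floor = db_floor, db_sum = isTRUE(db_sum),
    lat_floor = lat_floor, epsilon = epsilon,
    window_len = as.integer(window_len), calib_quantile = calib_quantile,
    calibration_contractions = as.integer(calibration_contractions),
    adapt_margin = adapt_margin, cort_margin = cort_margin,
    weight_mode = weight_mode, weight_lambda = weight_lambda,
    eeg_band = eeg_band, emg_band = emg_band, notch_band = notch_band,
    eeg_order = as.integer(eeg_order), emg_order = as.integer(emg_order),
    notch_order = as.integer(notch_order),
    eeg_causal = isTRUE(eeg_causal), emg_causal = isTRUE(emg_causal),
    artifact_mode = artifact_mode, winsor_k = winsor_k,
    match_window_s = match_window_s, fs = fs
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!(cfg$M > cfg$N && cfg$N >= 1)) {
    stop("Config requires M > N >= 1.", call. = FALSE)
  }
  if (cfg$Lw %% 2 != 1) stop("Config requires odd Lw.", call. = FALSE)
  if (cfg$window_len < 1) stop("Config requires window_len >= 1.", call. = FALSE)
  if (cfg$epsilon <= 0) stop("Config requires epsilon > 0.", call. = FALSE)
  if ((cfg$nW - 1L) * cfg$step + cfg$L_win > cfg$pretrigger_samples) {
    stop("Sliding-FFT windows exceed the pre-trigger buffer: ",
         "(nW-1)*step + L_win must be <= pretrigger_samples.", call. = FALSE)
  }
  if (cfg$calibration_contractions < cfg$window_len) {
    stop("calibration_contractions must be >= window_len.", call. = FALSE)
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  OOM windows M/N: ", x$M, "/", x$N, " samples, refractory ",
      x$refractory_ms, " ms\n", sep = "")
  cat("  MAP window Lw: ", x$Lw, " samples; pre-trigger buffer: ",
      x$pretrigger_samples, " samples\n", sep = "")
  cat("  sliding FFT: ", x$nW, " x ", x$L_win, "-sample windows, step ",
      x$step, " (", x$fs / x$L_win, " Hz resolution)\n", sep = "")
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat("  calibration: ", x$calibration_contractions, " contractions, q = ",
      x$calib_quantile, ", adaptive window ", x$window_len, "\n", sep = "")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Only keys present in the file override defaults, so partial configs are
#' valid. Band edge lists round-trip as named two-element vectors.
#'
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$bands)) raw$bands <- lapply(raw$bands, as.numeric)
  if (!is.null(raw$band_bins)) raw$band_bins <- lapply(raw$band_bins, as.numeric)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
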