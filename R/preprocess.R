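#' Butterworth band filtering and power-line notch
#'
#' The acquisition chain is replicated in software: EEG is band-passed
#' 1-40 Hz (8th-order Butterworth), EMG 15-250 Hz, and both get a 48-52 Hz
#' band-stop against power-line interference. Filters are applied zero-phase
#' (forward-backward, doubling the effective order) by default so that EEG
#' and EMG stay aligned; set `causal = TRUE` in the config for a single
#' causal pass emulating streaming.
#'
#' @param record an [mc_record()].
#' @param config a [pipeline_config()].
#' @param causal override the config's pass mode (notch only; the band
#'   filters follow `eeg_causal`/`emg_causal`).
#' @return A filtered [mc_record()] of identical shape.
#' @name preprocessing
NULL

apply_filter <- function(record, flt, causal) {
  out <- record
  for (i in seq_len(nrow(record$data))) {
    x <- record$data[i, ]
    out$data[i, ] <- if (causal) as.numeric(signal::filter(flt, x))
                     else signal::filtfilt(flt, x)
  }
  out
}

design_bandpass <- function(band, order, fs, clip_high = FALSE) {
  ny <- fs / 2
  hi <- band[2]
  if (hi >= ny) {
    if (!clip_high) {
      stop("Sampling rate ", fs, " Hz is too low for band ", band[1], "-",
           band[2], " Hz.", call. = FALSE)
    }
    hi <- 0.99 * ny  # EMG convention: clip the upper edge below Nyquist
  }
  if (!(band[1] > 0 && band[1] < hi)) {
    stop("Sampling rate ", fs, " Hz is too low for band ", band[1], "-",
         band[2], " Hz.", call. = FALSE)
  }
  # signal::butter() builds a band filter of order 2n from n
  signal::butter(order / 2, c(band[1], hi) / ny, type = "pass")
}

#' @rdname preprocessing
#' @export
bandpass_eeg <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "mc_record"))
  flt <- design_bandpass(config$eeg_band, config$eeg_order, record$fs)
  apply_filter(record, flt, config$eeg_causal)
}

#' @rdname preprocessing
#' @export
bandpass_emg <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "mc_record"))
  flt <- design_bandpass(config$emg_band, config$emg_order, record$fs,
                         clip_high = TRUE)
  apply_filter(record, flt, config$emg_causal)
}

#' @rdname preprocessing
#' @export
notch_power_line <- function(record, config = pipeline_config(),
                             causal = config$eeg_causal) {
  stopifnot(inherits(record, "mc_record"))
  ny <- record$fs / 2
  if (config$notch_band[2] >= ny) {
    stop("Sampling rate too low for a ", config$notch_band[1], "-",
         config$notch_band[2], " Hz notch.", call. = FALSE)
  }
  flt <- signal::butter(config$notch_order / 2, config$notch_band / ny,
                        type = "stop")
  apply_filter(record, flt, causal)
}

#' Resample a record to 500 Hz
#'
#' Downsamples to exactly 500 Hz (e.g. from a 2048 Hz acquisition node,
#' a non-integer 4.096 factor). Anti-aliasing is a zero-phase 8th-order
#' Butterworth low-pass at 0.45 x 500 Hz, after which the band-limited
#' signal is evaluated at the exact 500 Hz sample instants by cubic-spline
#' interpolation. Upsampling is refused.
#'
#' @param record an [mc_record()].
#' @param target_fs target rate, Hz.
#' @return An [mc_record()] at `target_fs`; returned unchanged if already
#'   at the target rate.
#' @export
resample_to_500 <- function(record, target_fs = 500) {
  stopifnot(inherits(record, "mc_record"))
  if (record$fs == target_fs) return(record)
  if (record$fs < target_fs) {
    stop("Record at ", record$fs, " Hz cannot be upsampled to ", target_fs,
         " Hz.", call. = FALSE)
  }
  n_in <- n_samples(record)
  lp <- signal::butter(4, (0.45 * target_fs) / (record$fs / 2), type = "low")
  t_in <- (seq_len(n_in) - 1) / record$fs
  n_out <- floor((n_in - 1) * target_fs / record$fs) + 1
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, nrow(record$data), n_out)
  for (i in seq_len(nrow(record$data))) {
    y <- signal::filtfilt(lp, record$data[i, ])
    out[i, ] <- stats::spline(t_in, y, xout = t_out, method = "fmm")$y
  }
  mc_record(out, record$channel_names, fs = target_fs,
            start_time_s = record$start_time_s)
}
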