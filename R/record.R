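#' Multichannel sampled-signal record
#'
#' Container for a block of synchronously sampled signals: a channels x
#' samples numeric matrix plus the sampling rate and the start time of the
#' first sample. All per-sample processing in the package (filtering, ON/OFF
#' binarization, spectral analysis) operates on these records; derived
#' features are returned as tibbles.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param channel_names character vector, one unique name per row of `data`.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time_s time of the first sample in seconds (default 0).
#'
#' @return An object of class `mc_record`.
#' @export
#' @examples
#' rec <- mc_record(matrix(rnorm(20), 2), c("C3", "C4"), fs = 500)
#' n_samples(rec)
mc_record <- function(data, channel_names, fs, start_time_s = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names)) {
    stop("`data` must have one row per channel name (", nrow(data), " rows, ",
         length(channel_names), " names).", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("Channel names must be unique; duplicated: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number.", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, channel_names = channel_names, fs = as.numeric(fs),
         start_time_s = as.numeric(start_time_s)),
    class = "mc_record"
  )
}

#' @export
print.mc_record <- function(x, ...) {
  cat("<mc_record> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 3), " s)\n",
      sep = "")
  cat("  channels: ", paste(utils::head(x$channel_names, 13), collapse = ", "),
      if (length(x$channel_names) > 13) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname mc_record
#' @param x an `mc_record`.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "mc_record"))
  ncol(x$data)
}

#' Extract one channel of a record as a numeric vector
#'
#' @param x an `mc_record`.
#' @param channel channel name.
#' @return Numeric vector of samples.
#' @export
channel_signal <- function(x, channel) {
  stopifnot(inherits(x, "mc_record"))
  if (!channel %in% x$channel_names) {
    stop("Channel '", channel, "' not present in record.", call. = FALSE)
  }
  x$data[channel, ]
}

#' Standard EEG/EMG channel map
#'
#' Names the 13 scalp sites (10-20 system) and 10 bilateral lower-limb
#' muscles the detector expects, and designates the two lateral
#' gastrocnemii as master-trigger muscles. The gastrocnemius anchors the
#' analysis because it activates specifically at midstance, so its ON edge
#' time-locks feature extraction to a well-defined gait phase.
#'
#' @param eeg_channels character vector of EEG site names (13 required).
#' @param emg_muscles character vector of muscle names (10 required),
#'   `<muscle>_<side>` with side `L`/`R`.
#' @param master_trigger_muscles subset of `emg_muscles` whose ON edges
#'   trigger per-contraction analysis.
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(
    eeg_channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                     "Cp5", "Cp1", "Cp2", "Cp6", "P3", "Pz", "P4"),
    emg_muscles = as.vector(outer(c("AT", "LG", "VM", "RF", "BF"),
                                  c("L", "R"), paste, sep = "_")),
    master_trigger_muscles = c("LG_L", "LG_R")) {
  eeg_channels <- as.character(eeg_channels)
  emg_muscles <- as.character(emg_muscles)
  if (length(eeg_channels) != 13 || anyDuplicated(eeg_channels)) {
    stop("`eeg_channels` must be 13 unique names.", call. = FALSE)
  }
  if (length(emg_muscles) != 10 || anyDuplicated(emg_muscles)) {
    stop("`emg_muscles` must be 10 unique names.", call. = FALSE)
  }
  if (!all(master_trigger_muscles %in% emg_muscles)) {
    stop("`master_trigger_muscles` must be a subset of `emg_muscles`.",
         call. = FALSE)
  }
  structure(
    list(eeg_channels = eeg_channels, emg_muscles = emg_muscles,
         master_trigger_muscles = master_trigger_muscles),
    class = "channel_map"
  )
}

#' Validate a record against a channel map
#'
#' Checks that every expected channel name is present in the record.
#'
#' @param record an `mc_record`.
#' @param map a `channel_map`.
#' @param what `"eeg"` or `"emg"`: which half of the map to check.
#' @return `record`, invisibly, with channels reordered to map order.
#' @export
validate_channels <- function(record, map, what = c("eeg", "emg")) {
  what <- match.arg(what)
  expected <- if (what == "eeg") map$eeg_channels else map$emg_muscles
  missing <- setdiff(expected, record$channel_names)
  if (length(missing)) {
    stop("Record is missing required ", what, " channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  record$data <- record$data[expected, , drop = FALSE]
  record$channel_names <- expected
  invisible(record)
}

#' Functional-group channel sets used for cortical generalization
#'
#' Four macro groups over the 13 monitored sites: supplementary motor area
#' (SMA), primary motor (M1), sensorimotor (S1) and posterior parietal (PPC).
#'
#' @return Named list of character vectors.
#' @export
cortical_groups <- function() {
  list(
    SMA = c("F3", "Fz", "F4"),
    M1  = c("C3", "Cz", "C4"),
    S1  = c("Cp5", "Cp1", "Cp2", "Cp6"),
    PPC = c("P3", "Pz", "P4")
  )
}
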