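#' Event label vocabulary
#'
#' Closed set of annotation labels: one perturbation class (`slip`) and the
#' activities-of-daily-life classes the detector must not flag.
#'
#' @return Character vector.
#' @export
event_labels <- function() {
  c("slip", "walk_step", "curve", "tug_sit", "tug_stand", "obstacle")
}

#' Read a multichannel signal file
#'
#' Supports delimited text (comma or tab, auto-detected; a `time_s` column
#' plus one column per channel) and 16-bit EDF. For text input the sampling
#' rate is inferred from the time column, which must be uniform to within
#' 1 ppm; for EDF it is taken from the record headers.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` (any delimited text) or
#'   `"edf"`.
#' @param map optional `channel_map`; when given, the corresponding channel
#'   set (`what`) is validated and reordered.
#' @param what which map half to validate against, `"eeg"` or `"emg"`.
#' @return An [mc_record()].
#' @export
read_signals <- function(path, format = c("auto", "csv", "edf"),
                         map = NULL, what = "eeg") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else read_signals_text(path)
  if (!is.null(map)) rec <- validate_channels(rec, map, what)
  rec
}

read_signals_text <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  cols <- strsplit(trimws(header), delim, fixed = TRUE)[[1]]
  if (anyDuplicated(cols)) {
    stop("Duplicated channel name(s) in header: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("Delimited signal files need a 'time_s' column.", call. = FALSE)
  }
  ch <- setdiff(names(df), "time_s")
  tt <- df$time_s
  if (length(tt) < 2) stop("Need at least two samples.", call. = FALSE)
  dt <- diff(tt)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("Non-uniform time steps (beyond 1 ppm); cannot infer fs.",
         call. = FALSE)
  }
  fs <- 1 / mean(dt)
  # snap to an integer rate when within 1 ppm, so 0.002-s steps give fs = 500
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  mc_record(t(as.matrix(df[ch])), ch, fs = fs, start_time_s = tt[1])
}

#' Write a multichannel signal file
#'
#' Text output stores full double precision; EDF quantizes each channel to
#' 16 bits over a physical range covering its data.
#'
#' @param record an [mc_record()].
#' @param path file path.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_signals <- function(record, path, format = c("auto", "csv", "tsv", "edf")) {
  stopifnot(inherits(record, "mc_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv"
              else "csv"
  }
  if (format == "edf") return(write_edf(record, path))
  n <- n_samples(record)
  df <- data.frame(time_s = record$start_time_s + (seq_len(n) - 1) / record$fs,
                   t(record$data), check.names = FALSE)
  utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal EDF (European Data Format) support ----------------------------
# 256-byte fixed header + 256 bytes per signal, then little-endian int16
# records. Written with 1-second records when the length divides evenly,
# otherwise a single record spanning the whole signal; either way
# samples_per_record / record_duration equals fs.

edf_num8 <- function(x, up) {
  # shortest representation of a bound fitting 8 chars that does not shrink
  # the covered range (round outward: up = TRUE for maxima)
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8 && ((up && as.numeric(s) >= x) ||
                          (!up && as.numeric(s) <= x))) {
      return(s)
    }
  }
  # fall back to nudging outward by one representable step
  step <- abs(x) * 1e-3 + 1e-3
  edf_num8(if (up) x + step else x - step, up)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(record, path) {
  n <- n_samples(record)
  ns <- nrow(record$data)
  fs <- record$fs
  if (n %% fs == 0 && fs == round(fs)) {
    n_rec <- n %/% fs
    dur <- 1
    spr <- as.integer(fs)
  } else {
    n_rec <- 1L
    dur <- n / fs
    spr <- n
  }
  pmin <- apply(record$data, 1, min)
  pmax <- apply(record$data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # the physical range is stored as 8 ASCII chars; widen the stringified
  # range outward so it still covers the data, and scale against the stored
  # (parsed-back) values, not the full-precision ones
  pmin_s <- vapply(pmin, edf_num8, "", up = FALSE)
  pmax_s <- vapply(pmax, edf_num8, "", up = TRUE)
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(vapply(x, edf_pad, "", width = width),
                                            collapse = ""),
                                     con, eos = NULL)
  wr("0", 8); wr("", 80); wr("", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44)
  wr(n_rec, 8); wr(sprintf("%.6g", dur), 8); wr(ns, 4)
  wr(record$channel_names, 16)
  wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(pmin_s, 8)
  wr(pmax_s, 8)
  wr(rep(dmin, ns), 8); wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80); wr(rep(spr, ns), 8); wr(rep("", ns), 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((record$data[i, idx] - pmin[i]) * scale[i]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("Mixed per-signal sampling rates are not supported.", call. = FALSE)
  }
  spr <- spr[1]
  fs <- spr / dur
  out <- matrix(0, ns, n_rec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr, size = 2, endian = "little",
                     signed = TRUE)
      out[i, idx] <- pmin[i] + (dig - dmin[i]) * scale[i]
    }
  }
  mc_record(out, labels, fs = fs)
}

# ---- annotations -----------------------------------------------------------

#' Read / write event annotations
#'
#' Annotations are tab-separated with columns `onset_s`, `duration_s`,
#' `label`, `side`. Labels come from [event_labels()]; `side` is `L`, `R` or
#' `NA`. Row order is preserved.
#'
#' @param path file path.
#' @return `read_annotations()` returns a tibble with the four columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(onset_s = "numeric",
                                         duration_s = "numeric",
                                         label = "character",
                                         side = "character"))
  validate_annotations(tibble::as_tibble(df))
}

#' @rdname read_annotations
#' @param events data frame of annotations.
#' @export
write_annotations <- function(events, path) {
  events <- validate_annotations(events)
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_annotations <- function(events) {
  need <- c("onset_s", "duration_s", "label", "side")
  if (!all(need %in% names(events))) {
    stop("Annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(events$label), event_labels())
  if (length(bad)) {
    stop("Unknown label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(event_labels(), collapse = ", "), call. = FALSE)
  }
  if (nrow(events) && any(events$onset_s < 0)) {
    stop("onset_s must be >= 0.", call. = FALSE)
  }
  if (nrow(events) && any(events$duration_s < 0)) {
    stop("duration_s must be >= 0.", call. = FALSE)
  }
  bad_side <- setdiff(unique(events$side[!is.na(events$side)]), c("L", "R"))
  if (length(bad_side)) {
    stop("side must be L, R or NA.", call. = FALSE)
  }
  tibble::as_tibble(events[, need])
}

#' Read a session manifest
#'
#' A session manifest is a small YAML file binding the separately acquired
#' EEG and EMG files (and optionally a truth annotation file), mirroring a
#' two-chain acquisition setup. Relative paths are resolved against the
#' manifest location.
#'
#' @param path manifest file path.
#' @return A list with `eeg`, `emg` [mc_record()]s and, when present, a
#'   `truth` annotation tibble.
#' @export
read_session <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$eeg) || is.null(m$emg)) {
    stop("Session manifest needs 'eeg' and 'emg' keys.", call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  out <- list(eeg = read_signals(resolve(m$eeg)),
              emg = read_signals(resolve(m$emg)))
  if (!is.null(m$truth)) out$truth <- read_annotations(resolve(m$truth))
  out
}
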