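#' Extract the pre-trigger EEG window
#'
#' Returns the `pretrigger_samples` (default 400, ~800 ms at 500 Hz) EEG
#' samples strictly preceding the master-trigger edge, one row per channel.
#'
#' @param eeg an [mc_record()] of preprocessed EEG.
#' @param mt_sample 1-based trigger sample index.
#' @param config a [pipeline_config()].
#' @return Channels x `pretrigger_samples` numeric matrix.
#' @export
extract_pretrigger_window <- function(eeg, mt_sample,
                                      config = pipeline_config()) {
  stopifnot(inherits(eeg, "mc_record"))
  P <- config$pretrigger_samples
  if (mt_sample - P < 1) {
    stop("Trigger at sample ", mt_sample, " has fewer than ", P,
         " samples of EEG history.", call. = FALSE)
  }
  eeg$data[, (mt_sample - P):(mt_sample - 1), drop = FALSE]
}

#' Attenuate artifacts in a pre-trigger window
#'
#' Pluggable cleaning step ahead of the spectral analysis. The default is
#' the identity (no cleaning). `"winsorize"` clips each channel at
#' `winsor_k` multiples of a reference per-channel SD (supplied from a
#' calibration stretch, or estimated from the window itself), a simple
#' guard against large transient artifacts. A user-supplied function
#' `window -> window` can be passed for external cleaners.
#'
#' @param window channels x samples matrix.
#' @param config a [pipeline_config()] (`artifact_mode`, `winsor_k`).
#' @param ref_sd optional numeric vector of per-channel reference SDs.
#' @param cleaner optional function overriding the built-in modes.
#' @return Matrix of the same shape.
#' @export
attenuate_artifacts <- function(window, config = pipeline_config(),
                                ref_sd = NULL, cleaner = NULL) {
  if (!is.null(cleaner)) return(cleaner(window))
  if (config$artifact_mode == "identity") return(window)
  sds <- if (is.null(ref_sd)) apply(window, 1, stats::sd) else ref_sd
  clip <- config$winsor_k * sds
  out <- window
  for (i in seq_len(nrow(window))) {
    out[i, ] <- pmin(pmax(window[i, ], -clip[i]), clip[i])
  }
  out
}

#' Sliding-window FFT power spectra
#'
#' Splits the pre-trigger window into `nW` overlapped `L_win`-sample windows
#' at offsets `0, step, ..., (nW-1)*step` and computes a one-sided
#' normalized power spectrum per window and channel. Bin spacing is
#' `fs / L_win` (2.5 Hz at the defaults). Powers are normalized so that the
#' per-window bin powers sum to the window's mean square (Parseval).
#'
#' @param window channels x samples matrix from
#'   [extract_pretrigger_window()].
#' @param config a [pipeline_config()].
#' @return List with `power` (channels x bins x windows array), `freq_hz`
#'   (bin center frequencies) and `offsets` (0-based window offsets).
#' @export
sliding_fft <- function(window, config = pipeline_config()) {
  L <- config$L_win; step <- config$step; nW <- config$nW
  n <- ncol(window)
  offsets <- (seq_len(nW) - 1L) * step
  if (max(offsets) + L > n) {
    stop("Sliding windows read past the buffer: last offset ", max(offsets),
         " + L_win ", L, " > ", n, " samples.", call. = FALSE)
  }
  n_bins <- L %/% 2L + 1L
  freq <- (seq_len(n_bins) - 1L) * config$fs / L
  pow <- array(0, dim = c(nrow(window), n_bins, nW),
               dimnames = list(rownames(window), NULL, NULL))
  for (w in seq_len(nW)) {
    seg <- window[, (offsets[w] + 1L):(offsets[w] + L), drop = FALSE]
    ft <- stats::mvfft(t(seg))            # L x channels
    p <- Mod(ft[seq_len(n_bins), , drop = FALSE])^2 / L^2
    # fold the negative frequencies so the one-sided sum preserves energy
    if (L %% 2L == 0L) {
      p[2:(n_bins - 1L), ] <- 2 * p[2:(n_bins - 1L), ]
    } else {
      p[2:n_bins, ] <- 2 * p[2:n_bins, ]
    }
    pow[, , w] <- t(p)
  }
  list(power = pow, freq_hz = freq, offsets = offsets)
}

#' Map band edges to FFT bin centers
#'
#' A bin belongs to a band iff its center frequency lies within
#' `[low - half_bin, high + half_bin]`, half a bin width (1.25 Hz at the
#' defaults) beyond the physiological edges, so every band keeps at least
#' two bins and the 4-40 Hz range is covered without gaps. Explicit per-band
#' bin lists in `config$band_bins` override the rule.
#'
#' @param freq_hz bin center frequencies from [sliding_fft()].
#' @param config a [pipeline_config()].
#' @return Named list of integer bin indices per band.
#' @export
band_bin_indices <- function(freq_hz, config = pipeline_config()) {
  half <- config$fs / config$L_win / 2
  idx <- lapply(names(config$bands), function(b) {
    if (!is.null(config$band_bins[[b]])) {
      out <- match(config$band_bins[[b]], freq_hz)
      if (anyNA(out)) {
        stop("band_bins for ", b, " name frequencies absent from the grid.",
             call. = FALSE)
      }
      return(out)
    }
    rng <- config$bands[[b]]
    which(freq_hz >= rng[1] - half & freq_hz <= rng[2] + half & freq_hz > 0)
  })
  names(idx) <- names(config$bands)
  empty <- names(idx)[lengths(idx) == 0]
  if (length(empty)) {
    stop("Band(s) with no FFT bins: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Band-multiplex sliding spectra into a channel x band x window tensor
#'
#' For each channel, band and window, converts every bin power to dB
#' (flooring at `db_floor` first, so zero power stays finite) and sums the
#' dB values of the bins belonging to the band. Set `db_sum = FALSE` in the
#' config to sum raw powers first and convert the band total once.
#'
#' @param spectra output of [sliding_fft()].
#' @param config a [pipeline_config()].
#' @return Channels x bands x windows numeric array.
#' @export
band_multiplex <- function(spectra, config = pipeline_config()) {
  bins <- band_bin_indices(spectra$freq_hz, config)
  pow <- spectra$power
  dims <- dim(pow)
  out <- array(0, dim = c(dims[1], length(bins), dims[3]),
               dimnames = list(dimnames(pow)[[1]], names(bins), NULL))
  for (b in seq_along(bins)) {
    sel <- pow[, bins[[b]], , drop = FALSE]
    if (config$db_sum) {
      out[, b, ] <- apply(10 * log10(pmax(sel, config$db_floor)), c(1, 3), sum)
    } else {
      out[, b, ] <- 10 * log10(pmax(apply(sel, c(1, 3), sum), config$db_floor))
    }
  }
  out
}

#' Per-band power-trend slopes via ordinary least squares
#'
#' For every channel and band, fits `y = q + m * t` over the `nW` window
#' measurements by closed-form OLS, with `t` the window end times in ms
#' (`step/fs*1000, ..., nW*step/fs*1000`; 20..400 ms at the defaults). The
#' slope `m` (dB/ms) is the cortical-involvement measure: sustained band
#' power build-up before the trigger yields positive slopes.
#'
#' @param tensor channels x bands x windows array from [band_multiplex()].
#' @param config a [pipeline_config()].
#' @return List of two channels x bands matrices, `m_hat` (slopes, dB/ms)
#'   and `q_hat` (intercepts, dB).
#' @export
estimate_slopes <- function(tensor, config = pipeline_config()) {
  nW <- dim(tensor)[3]
  if (nW < 2) stop("Need at least two windows to fit a trend.", call. = FALSE)
  t_ms <- fit_times_ms(config)[seq_len(nW)]
  if (stats::var(t_ms) == 0) stop("Degenerate time vector.", call. = FALSE)
  tc <- t_ms - mean(t_ms)
  denom <- sum(tc^2)
  nc <- dim(tensor)[1]; nb <- dim(tensor)[2]
  m_hat <- q_hat <- matrix(0, nc, nb,
                           dimnames = dimnames(tensor)[1:2])
  for (b in seq_len(nb)) {
    y <- matrix(tensor[, b, ], nc, nW)
    ybar <- rowMeans(y)
    m <- as.numeric(y %*% tc) / denom
    m_hat[, b] <- m
    q_hat[, b] <- ybar - m * mean(t_ms)
  }
  list(m_hat = m_hat, q_hat = q_hat)
}

#' Time abscissa of the trend fit, in ms
#'
#' One point per sliding window, spaced by the window hop: `step/fs` seconds
#' apart, ending at `nW * step / fs` (20 to 400 ms at the defaults).
#'
#' @param config a [pipeline_config()].
#' @return Numeric vector of length `nW`.
#' @export
fit_times_ms <- function(config = pipeline_config()) {
  seq_len(config$nW) * config$step / config$fs * 1000
}

#' Generalize channel slopes into functional-group slopes
#'
#' Sums the per-channel slopes over each functional group (SMA, M1, S1,
#' PPC) within each band: 4 x 5 values summarizing how widespread the
#' pre-trigger power build-up is.
#'
#' @param slopes output of [estimate_slopes()] (or its `m_hat` matrix).
#' @param groups named list of channel sets, as [cortical_groups()].
#' @return Groups x bands numeric matrix.
#' @export
generalize <- function(slopes, groups = cortical_groups()) {
  m <- if (is.list(slopes) && !is.null(slopes$m_hat)) slopes$m_hat else slopes
  out <- t(vapply(groups,
                  function(ch) colSums(m[ch, , drop = FALSE]),
                  numeric(ncol(m))))
  dimnames(out) <- list(names(groups), colnames(m))
  out
}

#' Left/right lateralization ratios per band
#'
#' Per band, the left hemisphere sum is `m(F3) + m(C3) + m(P3) +
#' mean(m(Cp1), m(Cp5))` and the right one the {F4, C4, P4, mean(Cp2, Cp6)}
#' analogue. Both sums are rectified at a small floor before the left/right
#' ratio, so the ratio is finite and equals 1 whenever both hemispheres show
#' no power increase (the comparison is meaningful only for increments).
#'
#' @param slopes output of [estimate_slopes()] (or its `m_hat` matrix).
#' @param config a [pipeline_config()] (`lat_floor`).
#' @return Named numeric vector, one strictly positive ratio per band.
#' @export
lateralize <- function(slopes, config = pipeline_config()) {
  m <- if (is.list(slopes) && !is.null(slopes$m_hat)) slopes$m_hat else slopes
  left <- m["F3", ] + m["C3", ] + m["P3", ] + (m["Cp1", ] + m["Cp5", ]) / 2
  right <- m["F4", ] + m["C4", ] + m["P4", ] + (m["Cp2", ] + m["Cp6", ]) / 2
  pmax(left, config$lat_floor) / pmax(right, config$lat_floor)
}

#' All cortical features for one contraction
#'
#' Convenience wrapper chaining window extraction, artifact attenuation,
#' sliding FFT, band multiplexing, slope estimation, generalization and
#' lateralization.
#'
#' @param eeg preprocessed EEG [mc_record()].
#' @param mt_sample 1-based trigger index.
#' @param config a [pipeline_config()].
#' @return List with `slopes` (full [estimate_slopes()] output),
#'   `group_slopes` (4 x 5) and `lat_ratios` (length 5).
#' @export
cortical_features <- function(eeg, mt_sample, config = pipeline_config()) {
  win <- extract_pretrigger_window(eeg, mt_sample, config)
  win <- attenuate_artifacts(win, config)
  tensor <- band_multiplex(sliding_fft(win, config), config)
  slopes <- estimate_slopes(tensor, config)
  list(slopes = slopes,
       group_slopes = generalize(slopes),
       lat_ratios = lateralize(slopes, config))
}
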