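#' Run the full detection pipeline on one session
#'
#' Offline streaming emulation of the detector: preprocessing, ON/OFF
#' binarization, master-trigger detection, then — contraction by
#' contraction, in onset order — muscular-pattern scoring, cortical slope
#' extraction, adaptive calibration and logic-network classification. No
#' stage looks ahead of a trigger's decision point except through the fixed
#' pre-trigger buffer, so results match a causal deployment of the same
#' rules.
#'
#' The first `calibration_contractions` triggers seed the per-leg weight
#' vectors (batch occurrence counting) and the adaptive thresholds;
#' decisions are suppressed for them. Every later contraction is scored and
#' classified; contractions not labeled a loss of balance feed the weight
#' update (config `weight_mode`) and the rolling threshold adaptation.
#'
#' @param eeg,emg [mc_record()]s (raw; preprocessed internally unless
#'   `preprocess = FALSE`).
#' @param config a [pipeline_config()].
#' @param map a [channel_map()].
#' @param preprocess apply filtering/resampling first.
#' @return A `lob_detection` object: list with `decisions` and `features`
#'   tibbles, the final `thresholds`, `weights` and the `config`.
#' @export
run_detect <- function(eeg, emg, config = pipeline_config(),
                       map = channel_map(), preprocess = TRUE) {
  stopifnot(inherits(eeg, "mc_record"), inherits(emg, "mc_record"))
  if (preprocess) {
    eeg <- resample_to_500(eeg, config$fs)
    emg <- resample_to_500(emg, config$fs)
    eeg <- notch_power_line(bandpass_eeg(eeg, config), config,
                            causal = config$eeg_causal)
    emg <- notch_power_line(bandpass_emg(emg, config), config,
                            causal = config$emg_causal)
  }
  eeg <- validate_channels(eeg, map, "eeg")
  emg <- validate_channels(emg, map, "emg")

  ooms <- compute_oom_record(emg, config)
  mt_l <- map$master_trigger_muscles[grepl("_L$", map$master_trigger_muscles)]
  mt_r <- map$master_trigger_muscles[grepl("_R$", map$master_trigger_muscles)]
  triggers <- detect_master_triggers(ooms[mt_l, ], ooms[mt_r, ], config)

  half <- (config$Lw - 1L) %/% 2L
  usable <- triggers$mt_sample - config$pretrigger_samples >= 1 &
    triggers$mt_sample - half >= 1 &
    triggers$mt_sample + half <= n_samples(emg)
  triggers <- triggers[usable, ]

  K <- config$calibration_contractions
  if (nrow(triggers) < K + 1) {
    warning("Only ", nrow(triggers), " usable contractions; need more than ",
            K, " to calibrate and classify. No decisions emitted.")
    return(empty_detection(config))
  }

  feats <- purrr::map(seq_len(nrow(triggers)), function(i) {
    mt <- triggers$mt_sample[i]
    cf <- cortical_features(eeg, mt, config)
    list(mt_sample = mt, side = triggers$side[i],
         map = extract_map(ooms, mt, config),
         group_slopes = cf$group_slopes, lat_ratios = cf$lat_ratios)
  })

  # --- calibration block: weights from occurrence counting, then thresholds
  wv <- weight_vectors(map$emg_muscles)
  for (i in seq_len(K)) {
    wv <- update_weights(wv, feats[[i]]$map, feats[[i]]$side,
                         mode = "batch_recount")
  }
  for (s in c("L", "R")) {
    if (wv$counts[s] == 0L) {
      other <- setdiff(c("L", "R"), s)
      warning("No ", s, "-side contractions in calibration; mirroring the ",
              other, "-side weights.")
      wv[[paste0("W_", s)]] <- mirror_weights(wv[[paste0("W_", other)]])
    }
  }
  calib_scores <- vapply(seq_len(K),
                         function(i) score_map(feats[[i]]$map, wv,
                                               feats[[i]]$side),
                         numeric(1))
  state <- threshold_state(config)
  state <- seed_calibration(state, calib_scores,
                            lapply(feats[seq_len(K)], `[[`, "group_slopes"))

  # --- streaming monitoring phase
  rows <- vector("list", nrow(triggers))
  for (i in seq_len(nrow(triggers))) {
    f <- feats[[i]]
    score <- if (i <= K) calib_scores[i] else score_map(f$map, wv, f$side)
    if (i <= K) {
      net <- tibble::tibble(MA = NA_integer_, F1 = NA_integer_,
                            F2 = NA_integer_, n_gf = NA_integer_,
                            n_lf = NA_integer_, label = NA_character_)
      phase <- "calibration"
    } else {
      net <- logic_network(score, f$group_slopes, f$lat_ratios, state)
      phase <- "monitoring"
      if (net$label != "loss_of_balance") {
        wv <- update_weights(wv, f$map, f$side, mode = config$weight_mode,
                             lambda = config$weight_lambda)
        state <- adapt_thresholds(state, score, f$group_slopes)
      }
    }
    gs <- f$group_slopes
    slope_row <- stats::setNames(as.list(as.numeric(gs)),
                                 paste0("m_", rep(rownames(gs), ncol(gs)),
                                        "_", rep(colnames(gs),
                                                 each = nrow(gs))))
    lat_row <- stats::setNames(as.list(f$lat_ratios),
                               paste0("lat_", names(f$lat_ratios)))
    rows[[i]] <- tibble::tibble(
      mt_sample = f$mt_sample, time_s = (f$mt_sample - 1) / config$fs,
      side = f$side, phase = phase, score = score,
      map_bits = paste(f$map, collapse = ""),
      !!!slope_row, !!!lat_row, !!!net
    )
  }
  features <- dplyr::bind_rows(rows)
  decisions <- dplyr::filter(features, .data$phase == "monitoring")
  decisions <- dplyr::transmute(
    decisions, mt_sample = .data$mt_sample,
    decision_time_s = .data$time_s, side = .data$side,
    score = .data$score, MA = .data$MA, F1 = .data$F1, F2 = .data$F2,
    label = .data$label)
  structure(list(decisions = decisions, features = features,
                 thresholds = state, weights = wv, config = config),
            class = "lob_detection")
}

mirror_weights <- function(w) {
  nm <- names(w)
  flipped <- ifelse(grepl("_L$", nm), sub("_L$", "_R", nm),
                    sub("_R$", "_L", nm))
  stats::setNames(as.numeric(w[flipped]), nm)
}

empty_detection <- function(config) {
  structure(list(decisions = tibble::tibble(), features = tibble::tibble(),
                 thresholds = threshold_state(config),
                 weights = weight_vectors(), config = config),
            class = "lob_detection")
}

#' @export
print.lob_detection <- function(x, ...) {
  n_mon <- sum(x$features$phase == "monitoring", na.rm = TRUE)
  n_lob <- sum(x$decisions$label == "loss_of_balance", na.rm = TRUE)
  cat("<lob_detection> ", nrow(x$features), " contractions (",
      nrow(x$features) - n_mon, " calibration, ", n_mon, " monitored); ",
      n_lob, " loss-of-balance decision(s)\n", sep = "")
  invisible(x)
}

#' Write the per-contraction feature and decision logs
#'
#' @param detection a `lob_detection`.
#' @param features_path,decisions_path output TSV paths (either may be
#'   `NULL` to skip).
#' @return `detection`, invisibly.
#' @export
write_detection_logs <- function(detection, features_path = NULL,
                                 decisions_path = NULL) {
  stopifnot(inherits(detection, "lob_detection"))
  if (!is.null(features_path)) {
    utils::write.table(detection$features, features_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(decisions_path)) {
    utils::write.table(detection$decisions, decisions_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(detection)
}
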