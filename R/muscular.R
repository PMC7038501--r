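#' Binarize an EMG channel into an ON/OFF activation pattern
#'
#' Moving-power binarization: at every sample the mean square of the last
#' `N` samples (instantaneous power, PN) is compared against the mean square
#' of the last `M` samples (adaptive threshold, PM). The sample is ON (1)
#' iff PN is strictly greater than PM, which tracks slow changes in muscle
#' tone (e.g. fatigue) without any absolute amplitude threshold. Samples
#' with fewer than `M` samples of history are OFF.
#'
#' The computation is a vectorized O(n) sliding update (cumulative sums of
#' squares), equivalent to recomputing both window means at every sample.
#'
#' @param x numeric vector, one preprocessed EMG channel.
#' @param config a [pipeline_config()] supplying `M` and `N`.
#' @return Integer vector of 0/1, same length as `x`.
#' @export
#' @examples
#' x <- c(rep(0, 125), rep(1, 125))
#' compute_oom(x)[250]  # short window power exceeds long window: ON
compute_oom <- function(x, config = pipeline_config()) {
  M <- config$M; N <- config$N
  n <- length(x)
  if (n < M) {
    stop("Signal (", n, " samples) shorter than the long window M = ", M, ".",
         call. = FALSE)
  }
  cs <- c(0, cumsum(x^2))
  t_idx <- M:n
  pm <- (cs[t_idx + 1] - cs[t_idx + 1 - M]) / M
  pn <- (cs[t_idx + 1] - cs[t_idx + 1 - N]) / N
  oom <- integer(n)
  # strict comparison: equality (e.g. all-zero input) is OFF. The absolute
  # power floor guards the scale-free comparison against float-noise
  # flicker in silent stretches (real front-ends have a quantization floor)
  oom[t_idx] <- as.integer(pn > pm & pn > config$power_floor)
  oom
}

#' ON/OFF patterns for every muscle of an EMG record
#'
#' @param emg an [mc_record()] of preprocessed EMG channels.
#' @param config a [pipeline_config()].
#' @return A muscles x samples 0/1 integer matrix with muscle row names.
#' @export
compute_oom_record <- function(emg, config = pipeline_config()) {
  stopifnot(inherits(emg, "mc_record"))
  out <- t(vapply(seq_len(nrow(emg$data)),
                  function(i) compute_oom(emg$data[i, ], config),
                  integer(n_samples(emg))))
  rownames(out) <- emg$channel_names
  out
}

#' Detect master triggers from the gastrocnemius ON/OFF patterns
#'
#' A master trigger is a 0-to-1 transition of either gastrocnemius pattern;
#' it anchors all per-contraction analysis because the gastrocnemius fires
#' specifically at midstance. Edges closer than `refractory_ms` to the last
#' accepted trigger (either side) are discarded; when both sides rise at the
#' same sample, the right side wins (documented tie-break).
#'
#' @param oom_left,oom_right 0/1 vectors for the left/right gastrocnemius.
#' @param config a [pipeline_config()] supplying `refractory_ms` and `fs`.
#' @return A tibble with columns `mt_sample` (1-based sample index of the ON
#'   edge) and `side` (`"L"`/`"R"`), in time order.
#' @export
detect_master_triggers <- function(oom_left, oom_right,
                                   config = pipeline_config()) {
  stopifnot(length(oom_left) == length(oom_right))
  rising <- function(o) which(diff(o) == 1) + 1L
  edges <- dplyr::bind_rows(
    tibble::tibble(mt_sample = rising(oom_right), side = "R"),
    tibble::tibble(mt_sample = rising(oom_left), side = "L")
  )
  # stable order: time, then R before L on exact ties
  edges <- edges[order(edges$mt_sample, edges$side != "R"), ]
  refractory <- config$refractory_ms / 1000 * config$fs
  keep <- logical(nrow(edges))
  last <- -Inf
  for (i in seq_len(nrow(edges))) {
    if (edges$mt_sample[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- edges$mt_sample[i]
    }
  }
  tibble::as_tibble(edges[keep, ])
}

#' Extract the muscular activity pattern (MAP) at a trigger
#'
#' Observes all ON/OFF patterns in an `Lw`-sample window centered on the
#' master-trigger edge ((Lw-1)/2 samples before and after; 11 samples,
#' i.e. 10 ms either side at 500 Hz). A muscle enters the pattern
#' (MAP entry 1) iff it is ON for strictly more than half of the window
#' (time-predominance rule).
#'
#' @param ooms muscles x samples 0/1 matrix from [compute_oom_record()].
#' @param mt_sample 1-based trigger sample index.
#' @param config a [pipeline_config()] supplying `Lw`.
#' @return Named integer 0/1 vector, one entry per muscle.
#' @export
extract_map <- function(ooms, mt_sample, config = pipeline_config()) {
  half <- (config$Lw - 1L) %/% 2L
  lo <- mt_sample - half
  hi <- mt_sample + half
  if (lo < 1 || hi > ncol(ooms)) {
    stop("MAP window [", lo, ", ", hi, "] out of bounds for ", ncol(ooms),
         " samples.", call. = FALSE)
  }
  frac <- rowMeans(ooms[, lo:hi, drop = FALSE])
  stats::setNames(as.integer(frac > 0.5), rownames(ooms))
}

#' Per-leg occurrence weight vectors
#'
#' One nonnegative weight per muscle and per triggering leg, estimated from
#' the muscular patterns observed at non-perturbation contractions. A weight
#' is the (possibly exponentially discounted) frequency with which the
#' muscle was contracted at that leg's master triggers, so the weight vector
#' encodes the subject's "standard" pattern for each leg separately,
#' absorbing left/right gait asymmetries.
#'
#' @param muscles character vector of muscle names (defines order).
#' @return A `weight_vectors` object.
#' @export
weight_vectors <- function(muscles = channel_map()$emg_muscles) {
  zero <- stats::setNames(numeric(length(muscles)), muscles)
  structure(
    list(W_R = zero, W_L = zero, counts = c(R = 0L, L = 0L),
         maps = list(R = list(), L = list())),
    class = "weight_vectors"
  )
}

#' @export
print.weight_vectors <- function(x, ...) {
  cat("<weight_vectors> absorbed contractions: R =", x$counts["R"],
      ", L =", x$counts["L"], "\n")
  print(round(rbind(W_R = x$W_R, W_L = x$W_L), 3))
  invisible(x)
}

#' Absorb a muscular pattern into the weight vectors
#'
#' Updates only the triggering side. In `batch_recount` mode every stored
#' pattern is kept and each weight is the exact fraction of stored patterns
#' with that muscle contracted; in `exponential` mode weights decay toward
#' the incoming pattern with rate `lambda` (geometric forgetting, suited to
#' streaming use). Only contractions the classifier did not label as a loss
#' of balance should be absorbed, so perturbations never contaminate the
#' standard pattern.
#'
#' @param wv a [weight_vectors()] object.
#' @param map named 0/1 vector from [extract_map()].
#' @param side `"L"` or `"R"`.
#' @param mode `"batch_recount"` or `"exponential"`.
#' @param lambda exponential learning rate.
#' @return The updated `weight_vectors`.
#' @export
update_weights <- function(wv, map, side, mode = c("batch_recount", "exponential"),
                           lambda = 1 / 15) {
  stopifnot(inherits(wv, "weight_vectors"), side %in% c("L", "R"))
  mode <- match.arg(mode)
  slot <- paste0("W_", side)
  muscles <- names(wv[[slot]])
  map <- as.numeric(map[muscles])
  if (anyNA(map)) stop("MAP does not cover all weighted muscles.", call. = FALSE)
  if (mode == "batch_recount") {
    wv$maps[[side]] <- c(wv$maps[[side]], list(map))
    wv$counts[side] <- wv$counts[side] + 1L
    wv[[slot]] <- stats::setNames(colMeans(do.call(rbind, wv$maps[[side]])),
                                  muscles)
  } else {
    if (wv$counts[side] == 0L) {
      wv[[slot]][] <- map  # first observation initializes the pattern
    } else {
      wv[[slot]] <- (1 - lambda) * wv[[slot]] + lambda * map
    }
    wv$counts[side] <- wv$counts[side] + 1L
  }
  wv
}

#' Score a muscular pattern against the learned weights
#'
#' Normalized weighted overlap: `sum(MAP * W) / sum(W)` with the weight
#' vector of the triggering leg. Standard steps score near 1; anomalous
#' co-contraction patterns that miss the normally active muscles score low.
#'
#' @param map named 0/1 vector from [extract_map()].
#' @param wv a [weight_vectors()] object with absorbed contractions.
#' @param side `"L"` or `"R"`.
#' @return Score in `[0, 1]`.
#' @export
score_map <- function(map, wv, side) {
  stopifnot(inherits(wv, "weight_vectors"), side %in% c("L", "R"))
  w <- wv[[paste0("W_", side)]]
  if (sum(w) <= 0) {
    stop("Uncalibrated weight vector for side ", side,
         " (all weights zero).", call. = FALSE)
  }
  m <- as.numeric(map[names(w)])
  sum(m * w) / sum(w)
}
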