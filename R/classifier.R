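#' Adaptive threshold state
#'
#' Holds the muscular-score lower threshold, the 4 x 5 upper thresholds on
#' the generalized cortical slopes, the lateralization tolerance and the
#' rolling feature history driving adaptation. Created unseeded; call
#' [seed_calibration()] before computing alerts.
#'
#' @param config a [pipeline_config()].
#' @param groups functional group names.
#' @param bands band names.
#' @return A `threshold_state` object.
#' @export
threshold_state <- function(config = pipeline_config(),
                            groups = names(cortical_groups()),
                            bands = names(config$bands)) {
  structure(
    list(
      ms_thr = NA_real_,
      cort_thr = matrix(NA_real_, length(groups), length(bands),
                        dimnames = list(groups, bands)),
      epsilon = config$epsilon,
      window_len = config$window_len,
      adapt_margin = config$adapt_margin,
      cort_margin = config$cort_margin,
      calib_quantile = config$calib_quantile,
      seeded = FALSE,
      hist_scores = numeric(0),
      hist_slopes = list()
    ),
    class = "threshold_state"
  )
}

#' @export
print.threshold_state <- function(x, ...) {
  cat("<threshold_state>", if (x$seeded) "seeded" else "unseeded", "\n")
  if (x$seeded) {
    cat("  muscular score threshold:", signif(x$ms_thr, 4), "\n")
    cat("  cortical slope thresholds (dB/ms):\n")
    print(signif(x$cort_thr, 3))
  }
  invisible(x)
}

#' Seed the adaptive thresholds from a calibration block
#'
#' From the first `K` contractions of unperturbed movement: the muscular
#' threshold is the `q`-quantile of the calibration scores (a conservative
#' lower bound on "standard" scores) minus the muscular safety margin, and
#' each cortical threshold the `1 - q` quantile of that group/band slope
#' plus the cortical margin. Detections are suppressed while the
#' calibration block is being collected.
#'
#' @param state a [threshold_state()].
#' @param scores numeric vector of `K >= window_len` muscular scores.
#' @param group_slopes list of `K` groups x bands slope matrices.
#' @return The seeded `threshold_state`.
#' @export
seed_calibration <- function(state, scores, group_slopes) {
  stopifnot(inherits(state, "threshold_state"))
  K <- length(scores)
  if (K < state$window_len) {
    stop("Calibration needs at least window_len = ", state$window_len,
         " contractions; got ", K, ".", call. = FALSE)
  }
  if (length(group_slopes) != K) {
    stop("scores and group_slopes must have equal length.", call. = FALSE)
  }
  q <- state$calib_quantile
  state$ms_thr <- unname(stats::quantile(scores, q)) - state$adapt_margin
  arr <- simplify2array(group_slopes)        # groups x bands x K
  state$cort_thr[] <- apply(arr, c(1, 2), stats::quantile, probs = 1 - q) +
    state$cort_margin
  state$hist_scores <- utils::tail(scores, state$window_len)
  state$hist_slopes <- utils::tail(group_slopes, state$window_len)
  state$seeded <- TRUE
  state
}

#' Adapt thresholds with one more contraction
#'
#' Pushes the new features into a rolling window of `window_len`
#' contractions and computes candidate thresholds as the rolling median
#' shifted by `adapt_margin`. Thresholds only move toward the "worst" value:
#' the muscular threshold can only decrease and each cortical threshold only
#' increase (unless `reset = TRUE`), so a block of low-score activity (e.g.
#' obstacle avoidance) permanently lowers the operating point rather than
#' oscillating with it.
#'
#' @param state a seeded [threshold_state()].
#' @param score muscular score of the new contraction.
#' @param group_slopes its groups x bands slope matrix.
#' @param reset if `TRUE`, thresholds jump to the candidates regardless of
#'   direction.
#' @return The updated `threshold_state`.
#' @export
adapt_thresholds <- function(state, score, group_slopes, reset = FALSE) {
  stopifnot(inherits(state, "threshold_state"))
  if (!state$seeded) stop("Threshold state is not seeded.", call. = FALSE)
  state$hist_scores <- utils::tail(c(state$hist_scores, score),
                                   state$window_len)
  state$hist_slopes <- utils::tail(c(state$hist_slopes, list(group_slopes)),
                                   state$window_len)
  cand_ms <- stats::median(state$hist_scores) - state$adapt_margin
  arr <- simplify2array(state$hist_slopes)
  cand_cort <- apply(arr, c(1, 2), stats::median) + state$cort_margin
  if (reset) {
    state$ms_thr <- cand_ms
    state$cort_thr[] <- cand_cort
  } else {
    state$ms_thr <- min(state$ms_thr, cand_ms)
    state$cort_thr[] <- pmax(state$cort_thr, cand_cort)
  }
  state
}

#' Binary alerts for one contraction
#'
#' The muscular alert MA fires iff the score is strictly below the muscular
#' threshold; a cortical alert fires for each group/band cell whose slope is
#' strictly above its threshold.
#'
#' @param score muscular score.
#' @param group_slopes groups x bands slope matrix.
#' @param state a seeded [threshold_state()].
#' @return List with `MA` (0/1) and `cort_alerts` (groups x bands 0/1
#'   matrix).
#' @export
compute_alerts <- function(score, group_slopes, state) {
  stopifnot(inherits(state, "threshold_state"))
  if (!state$seeded) stop("Threshold state is not seeded.", call. = FALSE)
  list(MA = as.integer(score < state$ms_thr),
       cort_alerts = matrix(as.integer(group_slopes > state$cort_thr),
                            nrow(state$cort_thr), ncol(state$cort_thr),
                            dimnames = dimnames(state$cort_thr)))
}

#' Level-1 generalization flags
#'
#' A band's generalization flag GF is set iff strictly more than 2 of the 4
#' functional groups alert in that band; the level-1 outcome F1 is set iff
#' strictly more than 2 of the 5 bands carry a flag — a widespread,
#' multi-band power build-up.
#'
#' @param cort_alerts groups x bands 0/1 matrix.
#' @return List with `GF` (named 0/1 vector per band) and `F1` (0/1).
#' @export
level1_flag <- function(cort_alerts) {
  gf <- as.integer(colSums(cort_alerts) > 2)
  names(gf) <- colnames(cort_alerts)
  list(GF = gf, F1 = as.integer(sum(gf) > 2))
}

#' Level-2 lateralization flags
#'
#' A band's lateralization flag LF is set iff its left/right ratio falls
#' strictly outside `[1 - epsilon, 1 + epsilon]`; the level-2 outcome F2 is
#' set iff strictly fewer than 2 flags are active — i.e. the build-up is
#' *not* lateralized, as expected for a reactive balance response rather
#' than an ordinary asymmetric movement.
#'
#' @param lat_ratios named numeric vector of per-band ratios.
#' @param epsilon tolerance around 1.
#' @return List with `LF` (named 0/1 vector) and `F2` (0/1).
#' @export
level2_flag <- function(lat_ratios, epsilon = 0.1) {
  lf <- as.integer(lat_ratios > 1 + epsilon | lat_ratios < 1 - epsilon)
  names(lf) <- names(lat_ratios)
  list(LF = lf, F2 = as.integer(sum(lf) < 2))
}

#' Final three-level decision
#'
#' Loss of balance iff the widespread-build-up flag F1, the
#' non-lateralization flag F2 and the muscular alert MA are all set;
#' otherwise the contraction is an activity of daily life.
#'
#' @param F1,F2,MA 0/1 flags.
#' @return `"loss_of_balance"` or `"adl"`.
#' @export
classify <- function(F1, F2, MA) {
  if (F1 == 1 && F2 == 1 && MA == 1) "loss_of_balance" else "adl"
}

#' Run the full logic network on one contraction's features
#'
#' @param score muscular score.
#' @param group_slopes groups x bands slope matrix.
#' @param lat_ratios per-band lateralization ratios.
#' @param state a seeded [threshold_state()].
#' @return Tibble row with the flags and the label.
#' @export
logic_network <- function(score, group_slopes, lat_ratios, state) {
  al <- compute_alerts(score, group_slopes, state)
  l1 <- level1_flag(al$cort_alerts)
  l2 <- level2_flag(lat_ratios, state$epsilon)
  tibble::tibble(
    MA = al$MA, F1 = l1$F1, F2 = l2$F2,
    n_gf = sum(l1$GF), n_lf = sum(l2$LF),
    label = classify(l1$F1, l2$F2, al$MA)
  )
}
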