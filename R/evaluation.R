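#' Match detections to ground-truth perturbations
#'
#' Greedy one-to-one matching in time order: each truth slip is matched to
#' the earliest unused loss-of-balance decision within `match_window_s`
#' after its onset. Unmatched decisions are false alarms; unmatched slips
#' are misses. The detection time (DT) of a match is the latency from truth
#' onset to the decision.
#'
#' @param decisions tibble with `decision_time_s` and `label` columns (from
#'   a `lob_detection`), or the `lob_detection` itself.
#' @param truth annotation tibble (see [read_annotations()]).
#' @param match_window_s maximum latency counted as a hit, seconds.
#' @return List with `matches` (tibble: `truth_onset_s`,
#'   `decision_time_s`, `dt_ms`), `false_alarms` (tibble of unmatched
#'   decisions) and `misses` (tibble of unmatched slips).
#' @export
match_events <- function(decisions, truth, match_window_s = 1.0) {
  if (inherits(decisions, "lob_detection")) decisions <- decisions$decisions
  det <- decisions[decisions$label == "loss_of_balance", , drop = FALSE]
  det <- det[order(det$decision_time_s), , drop = FALSE]
  slips <- truth[truth$label == "slip", , drop = FALSE]
  slips <- slips[order(slips$onset_s), , drop = FALSE]
  used <- logical(nrow(det))
  m_truth <- m_det <- numeric(0)
  for (k in seq_len(nrow(slips))) {
    ok <- which(!used &
                  det$decision_time_s >= slips$onset_s[k] &
                  det$decision_time_s <= slips$onset_s[k] + match_window_s)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      m_truth <- c(m_truth, slips$onset_s[k])
      m_det <- c(m_det, det$decision_time_s[ok[1]])
    }
  }
  list(
    matches = tibble::tibble(truth_onset_s = m_truth, decision_time_s = m_det,
                             dt_ms = (m_det - m_truth) * 1000),
    false_alarms = tibble::as_tibble(det[!used, , drop = FALSE]),
    misses = tibble::as_tibble(
      slips[!slips$onset_s %in% m_truth, , drop = FALSE])
  )
}

#' Sensitivity: correctly detected perturbations, percent
#'
#' `100 * n_detected / n_events`.
#'
#' @param n_detected number of truth perturbations matched by a detection.
#' @param n_events total number of perturbations (must be > 0).
#' @return Percentage.
#' @export
#' @examples
#' sensitivity(9, 10)  # 90
sensitivity <- function(n_detected, n_events) {
  if (n_events <= 0) stop("No perturbations to evaluate.", call. = FALSE)
  100 * n_detected / n_events
}

#' Specificity: correctly passed daily-life contractions, percent
#'
#' `100 * (n_adl - n_false_alarms) / n_adl`.
#'
#' @param n_adl total daily-life contractions evaluated (must be > 0).
#' @param n_false_alarms contractions wrongly flagged as loss of balance.
#' @return Percentage.
#' @export
#' @examples
#' specificity(372, 2)  # 99.4624
specificity <- function(n_adl, n_false_alarms) {
  if (n_adl <= 0) stop("No daily-life contractions to evaluate.", call. = FALSE)
  100 * (n_adl - n_false_alarms) / n_adl
}

#' Aggregate per-unit percentages into mean and sample SD
#'
#' Arithmetic mean and n-1 sample standard deviation, rounded to two
#' decimals (report parity). A single value has SD 0 by convention.
#'
#' @param values numeric vector of per-subject or per-task percentages.
#' @return Tibble with `mean`, `sd`, `n`.
#' @export
#' @examples
#' aggregate_metrics(c(90, 100, 90, 90, 90, 100))  # 93.33 +- 5.16
aggregate_metrics <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("Nothing to aggregate.", call. = FALSE)
  s <- if (length(values) > 1) stats::sd(values) else 0
  tibble::tibble(mean = round(mean(values), 2), sd = round(s, 2),
                 n = length(values))
}

#' Detection-time statistics
#'
#' Mean, sample SD (0 for a single match), maximum and minimum of the
#' matched detection times, in ms.
#'
#' @param dt_ms numeric vector of detection times in ms (e.g.
#'   `match_events(...)$matches$dt_ms`); must be non-empty.
#' @return Tibble with `mean_ms`, `sd_ms`, `max_ms`, `min_ms`, `n`.
#' @export
detection_time_stats <- function(dt_ms) {
  if (!length(dt_ms)) stop("No matched detections.", call. = FALSE)
  tibble::tibble(
    mean_ms = mean(dt_ms),
    sd_ms = if (length(dt_ms) > 1) stats::sd(dt_ms) else 0,
    max_ms = max(dt_ms), min_ms = min(dt_ms), n = length(dt_ms)
  )
}

#' Score one session end to end
#'
#' Convenience wrapper: matches a detection run against truth and returns
#' the per-session metric row. Specificity counts every monitored non-slip
#' contraction as a daily-life trial; a contraction is a false alarm if it
#' was flagged but not matched to a slip.
#'
#' @param detection a `lob_detection`.
#' @param truth annotation tibble.
#' @param match_window_s maximum truth-to-decision latency, seconds.
#' @return One-row tibble with counts, `se_pct`, `sp_pct` and DT stats.
#' @export
evaluate_session <- function(detection, truth, match_window_s = 1.0) {
  m <- match_events(detection, truth, match_window_s)
  n_slips <- sum(truth$label == "slip")
  n_hits <- nrow(m$matches)
  n_monitored <- nrow(detection$decisions)
  n_adl <- n_monitored - n_hits
  n_fa <- nrow(m$false_alarms)
  dt <- if (n_hits) detection_time_stats(m$matches$dt_ms) else
    tibble::tibble(mean_ms = NA_real_, sd_ms = NA_real_, max_ms = NA_real_,
                   min_ms = NA_real_, n = 0L)
  tibble::tibble(
    n_slips = n_slips, n_detected = n_hits, n_adl = n_adl,
    n_false_alarms = n_fa,
    se_pct = if (n_slips > 0) sensitivity(n_hits, n_slips) else NA_real_,
    sp_pct = if (n_adl > 0) specificity(n_adl, n_fa) else NA_real_,
    dt_mean_ms = dt$mean_ms, dt_sd_ms = dt$sd_ms,
    dt_max_ms = dt$max_ms, dt_min_ms = dt$min_ms
  )
}

#' Muscular-cortical feature plane
#'
#' One point per monitored contraction with coordinates (muscular score,
#' generalized SMA slope in the alpha band), plus the current operating
#' thresholds. Contractions flagged as losses of balance sit in the
#' low-score / high-slope corner.
#'
#' @param detection a `lob_detection` (or its `features` tibble plus a
#'   `threshold_state` via `state`).
#' @param state optional `threshold_state` when `detection` is a tibble.
#' @return Tibble with `score`, `m_SMA_alpha`, `label`, and attached
#'   attributes `ms_thr` / `cort_thr_sma_alpha`.
#' @export
feature_plane <- function(detection, state = NULL) {
  if (inherits(detection, "lob_detection")) {
    state <- detection$thresholds
    features <- detection$features
  } else {
    features <- detection
  }
  col_or <- function(nm, default) {
    if (nm %in% names(features)) features[[nm]] else default
  }
  out <- tibble::tibble(
    score = col_or("score", numeric(0)),
    m_SMA_alpha = col_or("m_SMA_alpha", numeric(0)),
    phase = col_or("phase", character(0)),
    label = col_or("label", character(0))
  )
  attr(out, "ms_thr") <- if (!is.null(state) && state$seeded) state$ms_thr else NA_real_
  attr(out, "cort_thr_sma_alpha") <-
    if (!is.null(state) && state$seeded) state$cort_thr["SMA", "alpha"] else NA_real_
  out
}

#' Reproduce published-style metric tables from detection counts
#'
#' Given per-unit counts (detected/total perturbations, correct/total
#' daily-life trials), recomputes the per-row percentages and their
#' aggregate mean and SD — the same arithmetic used for reported validation
#' tables.
#'
#' @param counts data frame with columns `detected` and `total` (or
#'   `correct` and `total`), one row per subject or task.
#' @param kind `"sensitivity"` or `"specificity"`.
#' @return List with `per_row` percentages and `aggregate` (mean/sd tibble).
#' @export
metrics_from_counts <- function(counts, kind = c("sensitivity", "specificity")) {
  kind <- match.arg(kind)
  hits <- if ("detected" %in% names(counts)) counts$detected else
    counts$correct
  per_row <- if (kind == "sensitivity") {
    mapply(sensitivity, hits, counts$total)
  } else {
    mapply(function(h, t) specificity(t, t - h), hits, counts$total)
  }
  list(per_row = round(per_row, 2), aggregate = aggregate_metrics(per_row))
}
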