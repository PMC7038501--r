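#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection run
#'
#' Returns the per-contraction decision table (monitoring phase only).
#'
#' @param x a `lob_detection`.
#' @param ... unused.
#' @return A tibble, one row per classified contraction.
#' @export
tidy.lob_detection <- function(x, ...) x$decisions

#' One-row summary of a detection run
#'
#' @param x a `lob_detection`.
#' @param ... unused.
#' @return Tibble with contraction counts, the flag rates and the final
#'   muscular threshold.
#' @export
glance.lob_detection <- function(x, ...) {
  mon <- x$features[x$features$phase == "monitoring", , drop = FALSE]
  tibble::tibble(
    n_contractions = nrow(x$features),
    n_calibration = sum(x$features$phase == "calibration"),
    n_monitored = nrow(mon),
    n_loss_of_balance = sum(mon$label == "loss_of_balance"),
    muscular_alert_rate = if (nrow(mon)) mean(mon$MA) else NA_real_,
    ms_thr = x$thresholds$ms_thr
  )
}

#' Tidy the adaptive threshold state
#'
#' @param x a `threshold_state`.
#' @param ... unused.
#' @return Tibble with one row per thresholded feature: the muscular score
#'   bound plus the 4 x 5 cortical slope bounds.
#' @export
tidy.threshold_state <- function(x, ...) {
  cort <- tidyr::pivot_longer(
    tibble::as_tibble(x$cort_thr, rownames = "group"),
    -"group", names_to = "band", values_to = "threshold")
  dplyr::bind_rows(
    tibble::tibble(group = "muscular", band = NA_character_,
                   threshold = x$ms_thr, direction = "lower"),
    dplyr::mutate(cort, direction = "upper")
  )
}

#' Tidy the learned weight vectors
#'
#' @param x a `weight_vectors`.
#' @param ... unused.
#' @return Tibble with `muscle`, `side`, `weight`.
#' @export
tidy.weight_vectors <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(muscle = names(x$W_R), side = "R", weight = unname(x$W_R)),
    tibble::tibble(muscle = names(x$W_L), side = "L", weight = unname(x$W_L))
  )
}
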