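#' Per-AOI percentage of total fixation time
#'
#' For each trial, the time fixated in each of the six labels (five AOIs plus
#' `outside`) is divided by the trial's total fixation time on the stimulus
#' and expressed as a percentage; per-participant values are then the
#' equal-weight mean across trials (`method = "per_trial"`, the default) or
#' computed from milliseconds pooled across trials (`method = "pooled"`).
#' Trials with zero fixation time carry no percentage and are excluded from
#' the average; a participant with no fixations at all is dropped with a
#' message so cohort pipelines can log the exclusion.
#'
#' The six percentages of each participant sum to 100; the five face-AOI
#' percentages alone sum to at most 100, the remainder being `outside` time.
#'
#' @param labeled Labeled fixation tibble from [label_fixations()].
#' @param method `"per_trial"` (average of per-trial percentages) or
#'   `"pooled"` (percentages of pooled milliseconds).
#' @return A tibble with one row per participant: `participant`,
#'   `pct_left_eye`, `pct_right_eye`, `pct_nose`, `pct_mouth`, `pct_outer`,
#'   `pct_outside`, and `n_trials` (trials entering the average).
#' @export
fixation_time_percent <- function(labeled, method = c("per_trial", "pooled")) {
  method <- match.arg(method)
  stopifnot("aoi" %in% names(labeled))
  by_trial <- labeled |>
    dplyr::count(.data$participant, .data$stimulus, .data$aoi,
                 wt = .data$duration_ms, name = "ms", .drop = FALSE) |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::mutate(total_ms = sum(.data$ms)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total_ms > 0)
  if (method == "per_trial") {
    per_part <- by_trial |>
      dplyr::mutate(pct = 100 * .data$ms / .data$total_ms) |>
      dplyr::group_by(.data$participant, .data$aoi) |>
      dplyr::summarise(pct = mean(.data$pct),
                       n_trials = dplyr::n(), .groups = "drop")
  } else {
    per_part <- by_trial |>
      dplyr::group_by(.data$participant, .data$aoi) |>
      dplyr::summarise(ms = sum(.data$ms), total_ms = sum(.data$total_ms),
                       n_trials = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(pct = 100 * .data$ms / .data$total_ms)
  }
  dropped <- setdiff(unique(labeled$participant), unique(per_part$participant))
  if (length(dropped) > 0) {
    inform(paste0("Excluded participant(s) with no fixation time: ",
                  paste(dropped, collapse = ", ")))
  }
  per_part |>
    dplyr::select("participant", "aoi", "pct", "n_trials") |>
    tidyr::pivot_wider(names_from = "aoi", values_from = "pct",
                       names_prefix = "pct_", values_fill = 0)
}

#' Left/right eye fixation-time ratio
#'
#' `left / (left + right)`: 0.50 means no lateral bias, values above 0.50 a
#' bias toward the viewer's-left eye. Scale-invariant, so it can be fed
#' either milliseconds or percentages. Undefined (NA) when both inputs are
#' zero; such participants are excluded from ratio analyses.
#'
#' @param left_pct,right_pct Non-negative fixation times (any common unit).
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where undefined.
#' @examples
#' left_right_ratio(6.4, 3.6) # 0.64
#' @export
left_right_ratio <- function(left_pct, right_pct) {
  stopifnot(all(left_pct >= 0, na.rm = TRUE), all(right_pct >= 0, na.rm = TRUE))
  total <- left_pct + right_pct
  ifelse(total > 0, left_pct / total, NA_real_)
}

#' Mean total fixation time on the stimulus
#'
#' Mean across trials of the summed fixation durations (all six labels,
#' including `outside`), in seconds. Only trials with at least one detected
#' fixation are observable in a fixation table and enter the mean.
#'
#' @param labeled Labeled (or unlabeled) fixation tibble.
#' @return Tibble `participant`, `total_fix_s`.
#' @export
total_fixation_time <- function(labeled) {
  labeled |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::summarise(trial_s = sum(.data$duration_ms) / 1000, .groups = "drop") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(total_fix_s = mean(.data$trial_s), .groups = "drop")
}

#' Full per-participant fixation-time metric table
#'
#' Combines [fixation_time_percent()], [left_right_ratio()] (computed from
#' the participant's mean left- and right-eye percentages) and
#' [total_fixation_time()] into the standard metrics table.
#'
#' @inheritParams fixation_time_percent
#' @return Tibble with columns `participant, pct_left_eye, pct_right_eye,
#'   pct_nose, pct_mouth, pct_outer, pct_outside, lr_ratio, total_fix_s,
#'   n_trials`.
#' @export
fixation_metrics <- function(labeled, method = c("per_trial", "pooled")) {
  pct <- fixation_time_percent(labeled, method)
  tot <- total_fixation_time(labeled)
  pct |>
    dplyr::mutate(lr_ratio = left_right_ratio(.data$pct_left_eye,
                                              .data$pct_right_eye)) |>
    dplyr::left_join(tot, by = "participant") |>
    dplyr::select("participant", "pct_left_eye", "pct_right_eye", "pct_nose",
                  "pct_mouth", "pct_outer", "pct_outside", "lr_ratio",
                  "total_fix_s", "n_trials")
}
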