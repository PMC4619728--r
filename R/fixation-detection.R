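#' Fixation detection configuration
#'
#' Parameters for the velocity-threshold (I-VT) classifier. The defaults —
#' a 35 deg/s saccade velocity threshold and a 100 ms minimum fixation
#' duration — are the standard settings for remote eye tracking of young
#' children at 60 Hz.
#'
#' @param velocity_threshold_deg_s Angular speed below which a sample counts
#'   as belonging to a fixation (degrees of visual angle per second).
#' @param min_fixation_ms Minimum duration for a run of slow samples to be
#'   kept as a fixation (milliseconds).
#' @param max_gap_interpolation_ms Invalid-sample gaps up to this length are
#'   linearly interpolated before classification; `0` disables interpolation,
#'   so any tracking loss splits candidate fixations.
#' @param smooth_window Centred moving-average window (in samples, odd) for
#'   the gaze coordinates before velocity computation; `1` disables
#'   smoothing.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(velocity_threshold_deg_s = 35,
                             min_fixation_ms = 100,
                             max_gap_interpolation_ms = 0,
                             smooth_window = 1L) {
  if (velocity_threshold_deg_s <= 0 || min_fixation_ms <= 0) {
    abort("Detection thresholds must be strictly positive.",
          class = "gazenet_config_error")
  }
  if (max_gap_interpolation_ms < 0) {
    abort("max_gap_interpolation_ms must be non-negative.",
          class = "gazenet_config_error")
  }
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    abort("smooth_window must be an odd positive integer.",
          class = "gazenet_config_error")
  }
  structure(
    list(velocity_threshold_deg_s = velocity_threshold_deg_s,
         min_fixation_ms = min_fixation_ms,
         max_gap_interpolation_ms = max_gap_interpolation_ms,
         smooth_window = smooth_window),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    "<detection_config> I-VT: %.0f deg/s threshold, >= %.0f ms, gap interp %.0f ms, smoothing %s\n",
    x$velocity_threshold_deg_s, x$min_fixation_ms, x$max_gap_interpolation_ms,
    if (x$smooth_window > 1) paste0(x$smooth_window, " samples") else "off"))
  invisible(x)
}

#' Per-sample angular gaze velocity
#'
#' Adds a `velocity_deg_s` column: a two-point backward difference between
#' each valid sample and the immediately preceding sample of the same trial,
#' converted from pixels to degrees of visual angle. The velocity is `NA`
#' where the sample or its predecessor is invalid, and at the first sample of
#' each trial.
#'
#' @param gaze Gaze tibble with cyclopean `x`, `y`, `valid` columns
#'   (see [combine_eyes()]); trials identified by `participant`, `stimulus`.
#' @param geometry A [screen_geometry()].
#' @param exact Use the arctangent conversion instead of the small-angle
#'   approximation.
#' @return `gaze` with `velocity_deg_s` appended.
#' @export
sample_velocity <- function(gaze, geometry = screen_geometry(), exact = FALSE) {
  if (!all(c("x", "y", "valid") %in% names(gaze))) {
    gaze <- combine_eyes(gaze)
  }
  gaze |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::mutate(velocity_deg_s = velocity_vec(
      dplyr::pick(dplyr::everything()), geometry, exact = exact)) |>
    dplyr::ungroup()
}

# backward-difference angular speed for one trial's samples (time-sorted)
velocity_vec <- function(trial, geometry, exact = FALSE) {
  dx <- c(NA, diff(trial$x))
  dy <- c(NA, diff(trial$y))
  dt_s <- c(NA, diff(trial$t_ms)) / 1000
  ok <- trial$valid & c(FALSE, head(trial$valid, -1))
  v <- px_to_degrees(dx, dy, geometry, exact = exact) / dt_s
  ifelse(ok, v, NA_real_)
}

# centred moving average, NA-tolerant at edges; window = 1 is identity
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

# linearly interpolate invalid runs no longer than max_gap_ms
interpolate_gaps <- function(trial, max_gap_ms) {
  r <- rle(trial$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == nrow(trial)) next # edge gaps cannot be bridged
    gap_ms <- trial$t_ms[i1 + 1L] - trial$t_ms[i0 - 1L]
    if (gap_ms > max_gap_ms) next
    tt <- trial$t_ms[i0:i1]
    frac <- (tt - trial$t_ms[i0 - 1L]) / gap_ms
    trial$x[i0:i1] <- trial$x[i0 - 1L] + frac * (trial$x[i1 + 1L] - trial$x[i0 - 1L])
    trial$y[i0:i1] <- trial$y[i0 - 1L] + frac * (trial$y[i1 + 1L] - trial$y[i0 - 1L])
    trial$valid[i0:i1] <- TRUE
  }
  trial
}

detect_fixations_trial <- function(trial, config, geometry) {
  if (config$max_gap_interpolation_ms > 0) {
    trial <- interpolate_gaps(trial, config$max_gap_interpolation_ms)
  }
  if (config$smooth_window > 1L) {
    trial$x[trial$valid] <- moving_average(trial$x[trial$valid], config$smooth_window)
    trial$y[trial$valid] <- moving_average(trial$y[trial$valid], config$smooth_window)
  }
  vel <- velocity_vec(trial, geometry)
  # a sample belongs to a candidate fixation when it is valid and not moving
  # faster than threshold; an undefined velocity (run start) never breaks a run
  slow <- trial$valid &
    (is.na(vel) | vel < config$velocity_threshold_deg_s)
  if (!any(slow)) return(NULL)
  dt <- stats::median(diff(trial$t_ms))
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    onset <- trial$t_ms[starts[k]]
    offset <- trial$t_ms[ends[k]] + dt # each sample covers one frame
    dur <- offset - onset
    if (dur < config$min_fixation_ms - 1e-6) return(NULL) # tolerate fp noise at the boundary
    tibble::tibble(
      onset_ms = onset, offset_ms = offset, duration_ms = dur,
      cx = mean(trial$x[idx]), cy = mean(trial$y[idx]),
      n_samples = length(idx)
    )
  })
  dplyr::bind_rows(out)
}

#' Detect fixations with a velocity-threshold (I-VT) classifier
#'
#' Classifies each valid gaze sample as fixational (angular speed below the
#' threshold) or saccadic, and returns maximal fixational runs lasting at
#' least the minimum duration. A fixation's centroid is the mean position of
#' its member samples; its duration counts one nominal sample period per
#' member sample. Invalid samples split candidate runs unless short-gap
#' interpolation is enabled in the config.
#'
#' @param gaze Gaze tibble (raw binocular or already combined); trials are
#'   identified by `participant` and `stimulus` columns.
#' @param config A [detection_config()].
#' @param geometry A [screen_geometry()].
#' @return A tibble of fixations: `participant, stimulus, onset_ms,
#'   offset_ms, duration_ms, cx, cy, n_samples`, time-ordered within trials.
#'   Trials with no qualifying run contribute no rows.
#' @examples
#' gaze <- render_raw_gaze(
#'   tibble::tibble(aoi = c("nose", "mouth"), duration_ms = c(400, 600)),
#'   default_aoi_set(), noise_sd_deg = 0, seed = 1
#' )
#' detect_fixations(gaze)
#' @export
detect_fixations <- function(gaze, config = detection_config(),
                             geometry = screen_geometry()) {
  stopifnot(inherits(config, "detection_config"))
  if (!all(c("x", "y", "valid") %in% names(gaze))) {
    gaze <- combine_eyes(gaze)
  }
  gaze |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::group_modify(function(trial, key) {
      res <- detect_fixations_trial(trial, config, geometry)
      if (is.null(res)) tibble::tibble() else res
    }) |>
    dplyr::ungroup()
}
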