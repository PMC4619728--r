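#' Markov scanpath model for one group
#'
#' Describes how a simulated participant scans a face: a first-order Markov
#' chain over the five face AOIs plus `outside`, log-normal fixation
#' durations, and the trial timing of the emulated paradigm (12 trials of
#' 3500 ms at 60 Hz; about 2 s of the trial is spent in fixations, the rest
#' in saccades and tracking loss, matching what remote tracking of
#' preschoolers typically yields).
#'
#' The default transition structure is symmetric across AOIs: from an AOI a
#' fixation repeats in the same AOI with probability `p_repeat`, strays
#' `outside` with probability `p_outside`, and otherwise moves to one of the
#' other four AOIs uniformly. An *anchor* AOI (see `anchor_aoi`,
#' `anchor_strength`) receives multiplicatively boosted inbound probability
#' and has its outbound repeat/outside probabilities shrunk, after which
#' rows are renormalized; this concentrates transitions into and out of the
#' anchor, raising its degree, strength and standardized weighted degree
#' centrality — the generator's operationalization of a facial feature that
#' organizes exploration.
#'
#' @param aoi_names Five AOI names (canonical order).
#' @param p_repeat Probability that the next fixation stays in the same AOI.
#' @param p_outside Probability of straying outside all face AOIs.
#' @param anchor_aoi Optional AOI name to anchor on.
#' @param anchor_strength Anchoring intensity in `[0, 1)`: inbound
#'   probabilities are multiplied by `1 / (1 - strength)` and the anchor's
#'   own repeat/outside mass is multiplied by `1 - strength`, before row
#'   renormalization. `0` is no anchoring.
#' @param left_eye_bias Lateral occupancy bias: inbound probabilities into
#'   `left_eye` are multiplied by this factor and those into `right_eye`
#'   divided by it (rows renormalized), shifting the share of fixation time
#'   between the two eyes. `1` is symmetric; values above 1 produce the
#'   leftward bias typical of face viewing.
#' @param transition_probs Optional explicit 6 x 6 row-stochastic matrix over
#'   `c(aoi_names, "outside")`, overriding the constructed one (the anchor
#'   transform is still applied).
#' @param initial_probs Optional length-6 initial distribution; default
#'   uniform over the five AOIs.
#' @param duration_meanlog,duration_sdlog Log-normal fixation-duration
#'   parameters (defaults give a median around 250 ms).
#' @param min_duration_ms Durations are floored here (fixations shorter than
#'   the detection minimum would never be observed).
#' @param fixation_budget_ms Target total fixation time per trial;
#'   fixations are drawn until their durations reach it.
#' @param trial_duration_ms,trials_per_participant,sampling_hz Trial timing.
#' @return An object of class `scanpath_model`.
#' @export
scanpath_model <- function(aoi_names = AOI_NAMES,
                           p_repeat = 0.50,
                           p_outside = 0.05,
                           anchor_aoi = NULL,
                           anchor_strength = 0,
                           left_eye_bias = 1,
                           transition_probs = NULL,
                           initial_probs = NULL,
                           duration_meanlog = log(250),
                           duration_sdlog = 0.4,
                           min_duration_ms = 100,
                           fixation_budget_ms = 2000,
                           trial_duration_ms = 3500,
                           trials_per_participant = 12,
                           sampling_hz = 60) {
  stopifnot(length(aoi_names) >= 2, p_repeat >= 0, p_outside >= 0,
            p_repeat + p_outside < 1, min_duration_ms > 0,
            fixation_budget_ms > 0, trial_duration_ms >= fixation_budget_ms)
  if (anchor_strength < 0 || anchor_strength >= 1) {
    abort("anchor_strength must lie in [0, 1).", class = "gazenet_config_error")
  }
  states <- c(aoi_names, "outside")
  k <- length(aoi_names)
  if (is.null(transition_probs)) {
    P <- matrix(0, k + 1, k + 1, dimnames = list(states, states))
    for (i in seq_len(k)) {
      P[i, ] <- (1 - p_repeat - p_outside) / (k - 1)
      P[i, i] <- p_repeat
      P[i, k + 1] <- p_outside
    }
    P[k + 1, seq_len(k)] <- (1 - p_outside) / k # leaving "outside"
    P[k + 1, k + 1] <- p_outside
  } else {
    P <- transition_probs
    stopifnot(identical(dim(P), c(k + 1L, k + 1L)))
    dimnames(P) <- list(states, states)
  }
  if (!is.null(anchor_aoi) && anchor_strength > 0) {
    if (!anchor_aoi %in% aoi_names) {
      abort("anchor_aoi must be one of the AOI names.", class = "gazenet_config_error")
    }
    a <- match(anchor_aoi, states)
    P[-a, a] <- P[-a, a] / (1 - anchor_strength) # boosted inbound
    P[a, a] <- P[a, a] * (1 - anchor_strength) # fewer repeats,
    P[a, k + 1] <- P[a, k + 1] * (1 - anchor_strength) # fewer strays out
    P <- P / rowSums(P)
  }
  if (left_eye_bias <= 0) {
    abort("left_eye_bias must be positive.", class = "gazenet_config_error")
  }
  if (left_eye_bias != 1 && all(c("left_eye", "right_eye") %in% states)) {
    P[, "left_eye"] <- P[, "left_eye"] * left_eye_bias
    P[, "right_eye"] <- P[, "right_eye"] / left_eye_bias
    P <- P / rowSums(P)
  }
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9))
  if (is.null(initial_probs)) {
    initial_probs <- c(rep(1 / k, k), 0)
  }
  stopifnot(length(initial_probs) == k + 1,
            abs(sum(initial_probs) - 1) < 1e-9)
  structure(
    list(aoi_names = aoi_names, states = states,
         transition_probs = P, initial_probs = initial_probs,
         .cdf = t(apply(P, 1, cumsum)),
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         min_duration_ms = min_duration_ms,
         fixation_budget_ms = fixation_budget_ms,
         trial_duration_ms = trial_duration_ms,
         trials_per_participant = trials_per_participant,
         sampling_hz = sampling_hz),
    class = "scanpath_model"
  )
}

#' @export
print.scanpath_model <- function(x, ...) {
  cat(sprintf("<scanpath_model> %d AOIs + outside, %d trials x %.0f ms @ %.0f Hz, fixation budget %.0f ms\n",
              length(x$aoi_names), x$trials_per_participant,
              x$trial_duration_ms, x$sampling_hz, x$fixation_budget_ms))
  invisible(x)
}

#' Generate one trial's AOI-labeled fixation plan
#'
#' Draws fixation labels from the model's Markov chain and durations from
#' its (floored) log-normal until the cumulative fixation time reaches the
#' per-trial budget; the slack up to the trial duration is then spread over
#' the inter-fixation gaps (saccades and tracking loss), fixing each
#' fixation's onset. A pure function of `(model, seed)` when a seed is
#' given.
#'
#' @param model A [scanpath_model()].
#' @param seed Optional integer seed for exact reproducibility.
#' @return Tibble `aoi, onset_ms, offset_ms, duration_ms`, time-ordered.
#' @export
generate_scanpath <- function(model, seed = NULL) {
  stopifnot(inherits(model, "scanpath_model"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_scanpath(model)))
  }
  p <- gen_plan(model)
  tibble::tibble(
    aoi = factor(p$aoi, levels = ALL_LABELS),
    onset_ms = p$onset_ms,
    offset_ms = p$offset_ms,
    duration_ms = p$duration_ms
  )
}

# plan generation core, returning plain vectors (hot path for simulations)
gen_plan <- function(model) {
  n_max <- ceiling(model$fixation_budget_ms / model$min_duration_ms)
  durs <- pmax(rlnorm(n_max, model$duration_meanlog, model$duration_sdlog),
               model$min_duration_ms)
  n_fix <- which(cumsum(durs) >= model$fixation_budget_ms)[1]
  if (is.na(n_fix)) n_fix <- n_max
  durs <- durs[seq_len(n_fix)]
  # trim the last fixation so the budget is met but never exceeded wildly
  over <- sum(durs) - model$fixation_budget_ms
  if (over > 0 && durs[n_fix] - over >= model$min_duration_ms) {
    durs[n_fix] <- durs[n_fix] - over
  }
  P <- model$transition_probs
  # inverse-CDF draws against precomputed row CDFs keep the chain cheap
  cdf <- model$.cdf %||% t(apply(P, 1, cumsum))
  k <- ncol(P)
  u <- runif(n_fix)
  st <- integer(n_fix)
  st[1] <- min(k, findInterval(u[1], cumsum(model$initial_probs),
                               left.open = TRUE) + 1L)
  for (i in seq_len(n_fix - 1L)) {
    st[i + 1L] <- min(k, findInterval(u[i + 1L], cdf[st[i], ],
                                      left.open = TRUE) + 1L)
  }
  gap_total <- model$trial_duration_ms - sum(durs)
  # every inter-fixation gap gets at least ~3 sample periods (a saccade is
  # never instantaneous); the slack is spread proportionally at random
  min_gap <- min(3000 / model$sampling_hz, gap_total / (n_fix + 1L))
  g <- runif(n_fix + 1L)
  gaps <- min_gap + (gap_total - (n_fix + 1L) * min_gap) * g / sum(g)
  onsets <- cumsum(gaps[seq_len(n_fix)]) + cumsum(c(0, durs[-n_fix]))
  list(aoi = model$states[st], onset_ms = onsets, offset_ms = onsets + durs,
       duration_ms = durs)
}

#' Render a fixation plan as a raw binocular gaze stream
#'
#' The inverse of [detect_fixations()], used for round-trip validation. Each
#' planned fixation is placed at a point drawn inside its AOI rectangle
#' (well away from the edges) plus a per-fixation accuracy offset of SD
#' `noise_sd_deg` — the slowly-varying calibration error remote trackers
#' exhibit — and sampled at the model rate with a small per-sample precision
#' jitter. Gaps between fixations become straight-line saccade samples when
#' fast enough to exceed the 35 deg/s class boundary by a wide margin, and
#' tracking loss (invalid samples) otherwise, so candidate runs always split.
#'
#' @param plan Fixation plan tibble (`aoi`, `duration_ms`, optionally
#'   `onset_ms`/`offset_ms`; if absent, fixations are laid out with 50 ms
#'   gaps).
#' @param aois An unexpanded [aoi_set()]; the record matching `stimulus` (or
#'   the set's single/`"default"` layout) is used.
#' @param geometry A [screen_geometry()].
#' @param noise_sd_deg Per-fixation accuracy offset SD, degrees.
#' @param precision_sd_deg Per-sample jitter SD, degrees.
#' @param sampling_hz Sampling rate.
#' @param participant,stimulus Ids stamped on the samples.
#' @param trial_duration_ms Total stream length; default covers the plan.
#' @param seed Optional seed.
#' @return A gaze sample tibble in the canonical raw format.
#' @export
render_raw_gaze <- function(plan, aois, geometry = screen_geometry(),
                            noise_sd_deg = 0.3, precision_sd_deg = 0.02,
                            sampling_hz = 60,
                            participant = "p1", stimulus = "1",
                            trial_duration_ms = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, render_raw_gaze(plan, aois, geometry, noise_sd_deg,
                            precision_sd_deg, sampling_hz, participant,
                            stimulus, trial_duration_ms)))
  }
  stopifnot(nrow(plan) >= 1)
  if (!"onset_ms" %in% names(plan)) {
    gaps <- 50
    onset <- cumsum(c(gaps, head(plan$duration_ms, -1) + gaps))
    plan$onset_ms <- onset
    plan$offset_ms <- onset + plan$duration_ms
  }
  stim_aois <- aois[aois$stimulus == stimulus, ]
  if (nrow(stim_aois) == 0 && "default" %in% aois$stimulus) {
    stim_aois <- aois[aois$stimulus == "default", ]
  }
  if (nrow(stim_aois) == 0 && length(unique(aois$stimulus)) == 1) {
    stim_aois <- aois
  }
  if (nrow(stim_aois) == 0) {
    abort(paste0("No AOI record for stimulus '", stimulus, "'."),
          class = "gazenet_data_error")
  }
  ppd <- px_per_degree(geometry)
  dt <- 1000 / sampling_hz
  if (is.null(trial_duration_ms)) {
    trial_duration_ms <- max(plan$offset_ms) + dt
  }
  # target point per fixation. Internal AOIs: central half of the rectangle,
  # clear of the edges so the accuracy offset stays within the 1-degree
  # expansion. "outer": a band along the bottom of the face bounding box,
  # which the default layout keeps free of internal features. "outside":
  # beyond the face, toward the screen edge.
  outer <- stim_aois[stim_aois$aoi == "outer", ]
  fw <- outer$x1 - outer$x0; fh <- outer$y1 - outer$y0
  target <- t(vapply(as.character(plan$aoi), function(lab) {
    if (lab == "outside") {
      c(outer$x1 + 2 * ppd["x"] + runif(1, 0, ppd["x"]),
        runif(1, outer$y0 + 0.2 * fh, outer$y1 - 0.2 * fh))
    } else if (lab == "outer") {
      c(runif(1, outer$x0 + 0.15 * fw, outer$x1 - 0.15 * fw),
        runif(1, outer$y0 + 0.90 * fh, outer$y0 + 0.94 * fh))
    } else {
      r <- stim_aois[stim_aois$aoi == lab, ]
      c(runif(1, r$x0 + 0.25 * (r$x1 - r$x0), r$x1 - 0.25 * (r$x1 - r$x0)),
        runif(1, r$y0 + 0.25 * (r$y1 - r$y0), r$y1 - 0.25 * (r$y1 - r$y0)))
    }
  }, numeric(2)))
  offset_xy <- cbind(rnorm(nrow(plan), 0, noise_sd_deg * ppd["x"]),
                     rnorm(nrow(plan), 0, noise_sd_deg * ppd["y"]))
  t_ms <- seq(0, trial_duration_ms - dt / 2, by = dt)
  n <- length(t_ms)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); valid <- rep(FALSE, n)
  centre <- target + offset_xy
  # snap fixation onsets to the sample grid so a planned duration of d ms
  # occupies exactly floor(d / dt) frames and survives the minimum-duration
  # cut on re-detection
  i0 <- pmax(1L, floor(plan$onset_ms / dt + 1e-9) + 1L)
  n_samp <- floor(plan$duration_ms / dt + 1e-9)
  fix_idx <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    idx <- seq.int(i0[i], min(n, i0[i] + n_samp[i] - 1L))
    fix_idx[[i]] <- idx
    x[idx] <- centre[i, 1] + rnorm(length(idx), 0, precision_sd_deg * ppd["x"])
    y[idx] <- centre[i, 2] + rnorm(length(idx), 0, precision_sd_deg * ppd["y"])
    valid[idx] <- TRUE
  }
  # gaps: straight-line saccade samples easing into the landing position
  # when each step clears the 35 deg/s class boundary by a wide margin,
  # tracking loss (invalid samples) otherwise -- so candidate runs always
  # split between fixations
  for (i in seq_len(nrow(plan) - 1L)) {
    lo <- max(fix_idx[[i]]) + 1L
    hi <- min(fix_idx[[i + 1L]]) - 1L
    if (lo > hi) next
    idx <- lo:hi
    d_deg <- px_to_degrees(centre[i + 1L, 1] - centre[i, 1],
                           centre[i + 1L, 2] - centre[i, 2], geometry)
    step_speed <- (d_deg / length(idx)) / (dt / 1000)
    if (step_speed > 1.5 * 35) {
      frac <- seq_along(idx) / length(idx) # last gap sample lands on target
      x[idx] <- centre[i, 1] + frac * (centre[i + 1L, 1] - centre[i, 1])
      y[idx] <- centre[i, 2] + frac * (centre[i + 1L, 2] - centre[i, 2])
      valid[idx] <- TRUE
    }
  }
  tibble::tibble(
    participant = participant, stimulus = stimulus, t_ms = t_ms,
    xl = x, yl = y, xr = x, yr = y, vl = valid, vr = valid
  )
}

#' Two-group cohort design
#'
#' Bundles a per-group [scanpath_model()] with group sizes and covariate
#' distributions. Defaults emulate a developmental case-control study:
#' groups of 20 (`ASD`) and 21 (`TD`); verbal and non-verbal mental age
#' normal with the case group about one SD below controls; a `left_eye`
#' anchor of strength 0.3 in the control group only, which is the injected
#' group difference every recovery test hunts for.
#'
#' @param group_labels Two group names; the first is the case group.
#' @param n_per_group Integer sizes, same order.
#' @param models Named list of [scanpath_model()] per group; default builds
#'   one per group from `anchor_aoi`/`anchor_strength`.
#' @param anchor_aoi AOI anchored in each group (named vector or single
#'   value), used only when `models` is `NULL`.
#' @param anchor_strength Named numeric per group, in `[0, 1)`.
#' @param left_eye_bias Named numeric per group: lateral occupancy bias
#'   passed to [scanpath_model()]. Defaults emulate a near-absent bias in
#'   the case group and a clear leftward bias in controls.
#' @param covariates Named list per group of `list(ca = c(mean, sd),
#'   nvma = c(mean, sd), vma = c(mean, sd))` in months.
#' @param p_male Named per-group probability a participant is male.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(group_labels = c("ASD", "TD"),
                          n_per_group = c(20L, 21L),
                          models = NULL,
                          anchor_aoi = "left_eye",
                          anchor_strength = c(ASD = 0, TD = 0.3),
                          left_eye_bias = c(ASD = 0.96, TD = 1.25),
                          covariates = list(
                            ASD = list(ca = c(40.7, 11.5), nvma = c(33.6, 12.6),
                                       vma = c(28.1, 13.6)),
                            TD = list(ca = c(43.9, 14.3), nvma = c(46.1, 14.5),
                                      vma = c(45.1, 13.5))),
                          p_male = c(ASD = 16 / 20, TD = 13 / 21)) {
  stopifnot(length(group_labels) == 2, length(n_per_group) == 2)
  if (any(n_per_group < 4)) {
    abort("Group sizes must be at least 4.", class = "gazenet_config_error")
  }
  if (is.null(models)) {
    if (length(anchor_aoi) == 1) {
      anchor_aoi <- setNames(rep(anchor_aoi, 2), group_labels)
    }
    models <- lapply(setNames(group_labels, group_labels), function(g) {
      scanpath_model(anchor_aoi = anchor_aoi[[g]],
                     anchor_strength = anchor_strength[[g]],
                     left_eye_bias = left_eye_bias[[g]])
    })
  }
  stopifnot(setequal(names(models), group_labels),
            setequal(names(covariates), group_labels))
  structure(
    list(group_labels = group_labels,
         n_per_group = setNames(as.integer(n_per_group), group_labels),
         models = models, covariates = covariates,
         p_male = p_male),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %s\n",
              paste(sprintf("%s n=%d", x$group_labels,
                            x$n_per_group[x$group_labels]), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Simulates every participant of a [cohort_design()]: per-trial fixation
#' plans from the group's Markov model, participant metadata from the
#' group's covariate distributions, and (optionally) rendered raw 60 Hz
#' gaze streams so the full pipeline — detection, labeling, metrics,
#' networks, statistics — can be run end to end. A pure function of
#' `(design, seed)`.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @param render If `TRUE`, also render raw gaze streams (slower); if
#'   `FALSE` only the labeled fixation plans are returned, which is what
#'   simulation studies of the downstream statistics need.
#' @param aois AOI set used for rendering (default [default_aoi_set()]).
#' @param geometry A [screen_geometry()].
#' @param noise_sd_deg Accuracy offset SD passed to [render_raw_gaze()].
#' @return A list of class `gaze_cohort`: `metadata` (tibble
#'   `id, group, ca_months, nvma_months, vma_months, sex`), `plans` (labeled
#'   fixation tibble with `participant, stimulus, aoi, onset_ms, offset_ms,
#'   duration_ms`), and `gaze` (raw sample tibble, or `NULL`).
#' @export
generate_cohort <- function(design, seed = 1L, render = FALSE,
                            aois = NULL, geometry = screen_geometry(),
                            noise_sd_deg = 0.3) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(as.integer(seed), {
    if (render && is.null(aois)) aois <- default_aoi_set(geometry)
    meta <- list(); plans <- list(); gaze <- list()
    pid <- 0L
    for (g in design$group_labels) {
      model <- design$models[[g]]
      cv <- design$covariates[[g]]
      for (j in seq_len(design$n_per_group[[g]])) {
        pid <- pid + 1L
        id <- sprintf("P%02d", pid)
        meta[[pid]] <- tibble::tibble(
          id = id, group = g,
          ca_months = max(6, rnorm(1, cv$ca[1], cv$ca[2])),
          nvma_months = max(6, rnorm(1, cv$nvma[1], cv$nvma[2])),
          vma_months = max(6, rnorm(1, cv$vma[1], cv$vma[2])),
          sex = ifelse(runif(1) < design$p_male[[g]], "M", "F")
        )
        pp <- lapply(seq_len(model$trials_per_participant),
                     function(s) gen_plan(model))
        n_per <- vapply(pp, function(p) length(p$aoi), integer(1))
        plans[[pid]] <- tibble::tibble(
          participant = id,
          stimulus = rep(as.character(seq_along(pp)), n_per),
          aoi = factor(unlist(lapply(pp, `[[`, "aoi"), use.names = FALSE),
                       levels = ALL_LABELS),
          onset_ms = unlist(lapply(pp, `[[`, "onset_ms"), use.names = FALSE),
          offset_ms = unlist(lapply(pp, `[[`, "offset_ms"), use.names = FALSE),
          duration_ms = unlist(lapply(pp, `[[`, "duration_ms"), use.names = FALSE)
        )
        if (render) {
          gaze[[pid]] <- dplyr::bind_rows(lapply(seq_along(pp), function(s) {
            plan <- tibble::as_tibble(pp[[s]][c("aoi", "onset_ms", "offset_ms",
                                                "duration_ms")])
            render_raw_gaze(plan, aois, geometry, noise_sd_deg,
                            sampling_hz = model$sampling_hz,
                            participant = id, stimulus = as.character(s),
                            trial_duration_ms = model$trial_duration_ms)
          }))
        }
      }
    }
    structure(
      list(metadata = dplyr::bind_rows(meta),
           plans = dplyr::bind_rows(plans),
           gaze = if (render) dplyr::bind_rows(gaze) else NULL),
      class = "gaze_cohort"
    )
  })
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("<gaze_cohort> %d participants, %d planned fixations%s\n",
              nrow(x$metadata), nrow(x$plans),
              if (!is.null(x$gaze)) sprintf(", %d raw samples", nrow(x$gaze))
              else " (plans only)"))
  invisible(x)
}
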