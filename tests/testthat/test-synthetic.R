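test_that("scanpath generation is a pure function of model and seed", {
  model <- scanpath_model()
  expect_identical(generate_scanpath(model, seed = 5),
                   generate_scanpath(model, seed = 5))
  a <- generate_cohort(cohort_design(n_per_group = c(4, 4)), seed = 9)
  b <- generate_cohort(cohort_design(n_per_group = c(4, 4)), seed = 9)
  expect_identical(a$plans, b$plans)
  expect_identical(a$metadata, b$metadata)
})

test_that("model invariants hold: stochastic rows, floored durations, trial budget", {
  model <- scanpath_model(anchor_aoi = "left_eye", anchor_strength = 0.3)
  expect_equal(rowSums(model$transition_probs), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (s in 1:10) {
    plan <- generate_scanpath(model, seed = s)
    expect_true(all(plan$duration_ms >= 100))
    expect_true(all(diff(plan$onset_ms) > 0))
    expect_lte(max(plan$offset_ms), 3500)
  }
  expect_error(scanpath_model(anchor_strength = 1),
               class = "gazenet_config_error")
  expect_error(scanpath_model(anchor_aoi = "chin", anchor_strength = 0.2),
               class = "gazenet_config_error")
})

test_that("a degenerate chain pinned to one AOI yields only that label", {
  P <- matrix(0, 6, 6); P[, 4] <- 1 # everything moves to the mouth
  init <- c(0, 0, 0, 1, 0, 0)
  model <- scanpath_model(transition_probs = P, initial_probs = init)
  plan <- generate_scanpath(model, seed = 2)
  expect_true(all(plan$aoi == "mouth"))
})

test_that("empirical transition frequencies converge to the chain", {
  model <- scanpath_model()
  n_trials <- 50000
  pairs <- withr::with_seed(13, {
    from <- vector("list", n_trials); to <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      labs <- as.character(generate_scanpath(model)$aoi)
      if (length(labs) < 2) next
      from[[k]] <- labs[-length(labs)]
      to[[k]] <- labs[-1]
    }
    table(factor(unlist(from), model$states), factor(unlist(to), model$states))
  })
  emp <- pairs / rowSums(pairs)
  expect_true(all(abs(emp - model$transition_probs) < 0.01))
})

test_that("anchoring boosts transitions into the anchor and renormalizes", {
  base <- scanpath_model()
  anch <- scanpath_model(anchor_aoi = "left_eye", anchor_strength = 0.3)
  expect_gt(anch$transition_probs["nose", "left_eye"],
            base$transition_probs["nose", "left_eye"])
  expect_lt(anch$transition_probs["left_eye", "left_eye"],
            base$transition_probs["left_eye", "left_eye"])
  expect_equal(rowSums(anch$transition_probs), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rendered gaze reproduces the plan: constant at zero noise, recoverable with noise", {
  aois <- default_aoi_set()
  plan1 <- tibble::tibble(aoi = "nose", duration_ms = 500)
  g <- render_raw_gaze(plan1, aois, noise_sd_deg = 0, precision_sd_deg = 0,
                       seed = 3)
  on <- g[g$vl, ]
  expect_identical(length(unique(on$xl)), 1L)
  expect_identical(length(unique(on$yl)), 1L)

  plan5 <- tibble::tibble(
    aoi = c("left_eye", "nose", "mouth", "right_eye", "outer"),
    duration_ms = c(300, 250, 400, 200, 300))
  g5 <- render_raw_gaze(plan5, aois, seed = 4)
  fix <- detect_fixations(g5)
  expect_identical(nrow(fix), 5L)
  lab <- label_fixations(fix, aois)
  expect_identical(as.character(lab$aoi), plan5$aoi)
})

test_that("recovered centroids sit within three standard errors of the planned points", {
  aois <- default_aoi_set()
  geom <- screen_geometry()
  ppd <- px_per_degree(geom)
  plan <- tibble::tibble(aoi = c("nose", "mouth"), duration_ms = c(600, 600))
  reps <- 40
  err <- withr::with_seed(21, {
    vapply(seq_len(reps), function(i) {
      g <- render_raw_gaze(plan, aois, noise_sd_deg = 0.3,
                           precision_sd_deg = 0.02)
      fix <- detect_fixations(g)
      if (nrow(fix) != 2) return(NA_real_)
      # the accuracy offset is the dominant error; mean abs offset in x
      mean(abs(fix$cx - c(mean(g$xl[g$vl][1:36]), mean(tail(g$xl[g$vl], 36)))))
    }, numeric(1))
  })
  # centroid of samples equals the rendered centre up to precision jitter:
  # SE = 0.02 deg / sqrt(36) per fixation
  se_px <- 0.02 * ppd["x"] / sqrt(36)
  expect_true(mean(err, na.rm = TRUE) < 3 * se_px)
})

test_that("the default cohort has the designed size and structure", {
  co <- generate_cohort(cohort_design(), seed = 1)
  expect_identical(nrow(co$metadata), 41L)
  expect_identical(sum(co$metadata$group == "ASD"), 20L)
  expect_identical(sum(co$metadata$group == "TD"), 21L)
  trials <- co$plans |>
    dplyr::distinct(participant, stimulus) |>
    dplyr::count(participant)
  expect_true(all(trials$n == 12))
  expect_true(all(co$metadata$vma_months > 0))
})

test_that("the injected lateral bias is recovered end to end with high power", {
  # default design: case group near-symmetric, controls biased to the left
  # eye; the ratio analysis should find the difference in the right
  # direction well over 80% of the time at n = 20/21
  hits <- vapply(1:50, function(r) {
    co <- generate_cohort(cohort_design(), seed = 90000 + r)
    met <- fixation_metrics(co$plans) |>
      dplyr::inner_join(dplyr::rename(co$metadata, participant = id),
                        by = "participant")
    tt <- stats::t.test(lr_ratio ~ group, data = met)
    m <- tapply(met$lr_ratio, met$group, mean, na.rm = TRUE)
    m["TD"] > m["ASD"] && tt$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
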