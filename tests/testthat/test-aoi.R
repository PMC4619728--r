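geom <- screen_geometry()
ppd <- px_per_degree(geom)

simple_set <- function() {
  aoi_set(tibble::tibble(
    stimulus = "1",
    aoi = c("left_eye", "right_eye", "nose", "mouth", "outer"),
    x0 = c(100, 270, 200, 150, 0),
    y0 = c(100, 100, 200, 320, 0),
    x1 = c(240, 410, 320, 370, 520),
    y1 = c(180, 180, 300, 400, 500),
    internal = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  ))
}

test_that("AOI expansion grows rectangles by the pixel equivalent per side", {
  one <- simple_set()[1, ]
  # zero expansion is the identity
  expect_equal(expand_aoi(one, 0, geom), one)
  # a 100 x 100 px AOI expanded by 1 degree gains ~31 px per side on x
  sq <- one
  sq$x0 <- 200; sq$x1 <- 300; sq$y0 <- 200; sq$y1 <- 300
  grown <- expand_aoi(sq, 1, geom)
  expect_equal(grown$x1 - grown$x0, 100 + 2 * ppd["x"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(grown$y1 - grown$y0, 100 + 2 * ppd["y"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(grown$x1 - grown$x0, 162, tolerance = 1)
})

test_that("expansion clips at stimulus bounds and skips non-internal AOIs", {
  edge <- simple_set()[1, ]
  edge$x0 <- 5; edge$y0 <- 5
  grown <- expand_aoi(edge, 1, geom)
  expect_gte(grown$x0, 0)
  expect_gte(grown$y0, 0)
  outer <- simple_set()[5, ]
  expect_warning(same <- expand_aoi(outer, 1, geom), "not internal")
  expect_equal(same, outer)
})

test_that("expanding by d then e equals expanding by d + e before clipping", {
  one <- simple_set()[3, ]
  big <- c(0, 0, 1e6, 1e6) # effectively no clipping
  twice <- expand_aoi(expand_aoi(one, 0.4, geom, bounds = big), 0.6, geom,
                      bounds = big)
  once <- expand_aoi(one, 1.0, geom, bounds = big)
  expect_equal(twice, once, tolerance = 1e-9)
})

test_that("fixation assignment is total, closed on edges, and resolves overlaps by nearest centre", {
  aois <- simple_set()
  # rectangle centre and edges map to the AOI; far point maps outside
  expect_identical(assign_fixation(170, 140, aois), "left_eye")
  expect_identical(assign_fixation(100, 100, aois), "left_eye") # corner is inside
  expect_identical(assign_fixation(600, 600, aois), "outside")
  # interior non-feature face area is the outer AOI
  expect_identical(assign_fixation(50, 450, aois), "outer")

  # 1-degree expansion makes the eye AOIs overlap; nearest centre wins,
  # equidistant points fall to canonical order (left before right)
  grown <- expand_aois(aois, 1, geom)
  le <- grown[grown$aoi == "left_eye", ]
  re <- grown[grown$aoi == "right_eye", ]
  expect_lt(re$x0, le$x1) # the overlap exists
  px <- 250 # inside both; centres at x = 170 and 340, so nearer the left eye
  expect_identical(assign_fixation(px, 140, grown), "left_eye")
  expect_identical(assign_fixation(330, 140, grown), "right_eye")
  expect_identical(assign_fixation(255, 140, grown), "left_eye") # tie
})

test_that("label_scanpath preserves order and matches per-fixation assignment", {
  aois <- simple_set()
  fix <- tibble::tibble(
    participant = "p1", stimulus = "1",
    onset_ms = c(0, 200, 400, 600, 800),
    offset_ms = c(150, 350, 550, 750, 950),
    duration_ms = 150,
    cx = c(140, 380, 260, 260, 900),
    cy = c(140, 140, 250, 360, 700)
  )
  lab <- label_fixations(fix, aois, expansion_deg = 1, geom)
  expect_identical(nrow(lab), 5L)
  grown <- expand_aois(aois, 1, geom)
  expect_identical(as.character(lab$aoi),
                   assign_fixation(fix$cx, fix$cy, grown))
  expect_identical(as.character(lab$aoi),
                   c("left_eye", "right_eye", "nose", "mouth", "outside"))
  # empty input gives an empty labeled table
  expect_identical(nrow(label_fixations(fix[0, ], aois, 1, geom)), 0L)
})

test_that("aoi_set validation rejects malformed sets and JSON round-trips", {
  bad <- simple_set()
  bad$aoi[5] <- "chin"
  expect_error(aoi_set(bad), class = "gazenet_data_error")
  flipped <- simple_set()
  flipped$x1[1] <- flipped$x0[1] - 10
  expect_error(aoi_set(flipped), class = "gazenet_data_error")

  aois <- default_aoi_set(geom, stimuli = c("1", "2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_aoi_json(aois, path)
  back <- read_aoi_json(path)
  expect_equal(dplyr::arrange(tibble::as_tibble(back), stimulus, aoi),
               dplyr::arrange(tibble::as_tibble(aois), stimulus, aoi),
               tolerance = 1e-9)
})
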