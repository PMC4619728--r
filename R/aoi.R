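#' Construct and validate an AOI set
#'
#' An AOI set is a tibble with one row per rectangular area of interest:
#' columns `stimulus`, `aoi`, `x0`, `y0`, `x1`, `y1`, `internal`. Coordinates
#' are stimulus pixels, origin top-left, y downward; rectangles are closed
#' (edge points are inside). Each stimulus must carry exactly the five
#' canonical face AOIs: `left_eye`, `right_eye`, `nose`, `mouth`, `outer`.
#'
#' Naming convention: `left_eye` is the eye on the *viewer's* left side of
#' the image (the face's own right eye). All lateral results in this package
#' follow this viewer-centred convention.
#'
#' The four internal-feature AOIs (`internal = TRUE`) are eligible for
#' expansion by a visual angle ([expand_aois()]); `outer` is the face
#' bounding rectangle and is labelled only when no internal AOI matches, so
#' it approximates the non-rectangular "outer facial features" region.
#'
#' @param aois A data frame with the columns above (`internal` optional:
#'   defaults to `TRUE` for all but `outer`).
#' @return A validated `aoi_set` tibble.
#' @export
aoi_set <- function(aois) {
  aois <- tibble::as_tibble(aois)
  required <- c("stimulus", "aoi", "x0", "y0", "x1", "y1")
  missing <- setdiff(required, names(aois))
  if (length(missing) > 0) {
    abort(paste0("AOI set is missing column(s): ", paste(missing, collapse = ", ")),
          class = "gazenet_format_error")
  }
  if (!"internal" %in% names(aois)) {
    aois$internal <- aois$aoi != "outer"
  }
  aois <- dplyr::mutate(aois, stimulus = as.character(.data$stimulus))
  bad_rect <- aois$x0 >= aois$x1 | aois$y0 >= aois$y1
  if (any(bad_rect)) {
    abort("AOI rectangles must satisfy x0 < x1 and y0 < y1.",
          class = "gazenet_data_error")
  }
  chk <- aois |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(ok = setequal(.data$aoi, AOI_NAMES) &&
                       !anyDuplicated(.data$aoi), .groups = "drop")
  if (any(!chk$ok)) {
    abort(paste0("Each stimulus needs exactly the five canonical AOIs (",
                 paste(AOI_NAMES, collapse = ", "), "); offending stimulus: ",
                 paste(chk$stimulus[!chk$ok], collapse = ", ")),
          class = "gazenet_data_error")
  }
  class(aois) <- c("aoi_set", class(tibble::tibble()))
  aois
}

#' A synthetic default AOI set for a centred face
#'
#' Builds plausible rectangles for the five canonical AOIs of a frontal face
#' subtending about 19 x 20 degrees at the centre of the screen. These are
#' synthetic coordinates for testing and simulation — they are not measured
#' from any particular stimulus set.
#'
#' @param geometry A [screen_geometry()]; the face is centred on this screen.
#' @param stimuli Character vector of stimulus ids sharing the layout.
#' @return An `aoi_set` tibble.
#' @export
default_aoi_set <- function(geometry = screen_geometry(),
                            stimuli = as.character(1:12)) {
  ppd <- px_per_degree(geometry)
  cx <- geometry$resolution_px[1] / 2
  cy <- geometry$resolution_px[2] / 2
  fw <- unname(19 * ppd["x"]) # face width in px
  fh <- unname(20 * ppd["y"])
  rect <- function(name, rx0, ry0, rx1, ry1, internal = TRUE) {
    tibble::tibble(
      aoi = name,
      x0 = cx - fw / 2 + rx0 * fw, y0 = cy - fh / 2 + ry0 * fh,
      x1 = cx - fw / 2 + rx1 * fw, y1 = cy - fh / 2 + ry1 * fh,
      internal = internal
    )
  }
  one <- dplyr::bind_rows(
    rect("left_eye",  0.16, 0.28, 0.44, 0.42),
    rect("right_eye", 0.56, 0.28, 0.84, 0.42),
    rect("nose",      0.38, 0.42, 0.62, 0.62),
    rect("mouth",     0.30, 0.66, 0.70, 0.80),
    rect("outer",     0.00, 0.00, 1.00, 1.00, internal = FALSE)
  )
  aoi_set(tidyr::crossing(stimulus = stimuli, one))
}

#' Expand an AOI rectangle by a visual angle
#'
#' Grows a rectangle by the pixel equivalent of `expansion_deg` on each of
#' its four sides, then clips it to the stimulus bounds. Only
#' internal-feature AOIs are eligible; a non-internal AOI is returned
#' unchanged with a warning. Expanding by d then by e equals expanding by
#' d + e (before clipping).
#'
#' @param aoi A one-row AOI data frame (`aoi, x0, y0, x1, y1, internal`).
#' @param expansion_deg Expansion in degrees of visual angle per side.
#' @param geometry A [screen_geometry()] used for the pixel conversion and
#'   (by default) the clipping bounds.
#' @param bounds Numeric `c(x0, y0, x1, y1)` clipping rectangle; defaults to
#'   the full screen.
#' @return The expanded one-row AOI data frame.
#' @export
expand_aoi <- function(aoi, expansion_deg, geometry = screen_geometry(),
                       bounds = NULL) {
  stopifnot(nrow(aoi) == 1, expansion_deg >= 0)
  if (!isTRUE(aoi$internal)) {
    warn(paste0("AOI '", aoi$aoi, "' is not internal; returned unchanged."))
    return(aoi)
  }
  if (is.null(bounds)) bounds <- c(0, 0, geometry$resolution_px)
  ppd <- px_per_degree(geometry)
  aoi$x0 <- max(bounds[1], aoi$x0 - expansion_deg * ppd["x"])
  aoi$y0 <- max(bounds[2], aoi$y0 - expansion_deg * ppd["y"])
  aoi$x1 <- min(bounds[3], aoi$x1 + expansion_deg * ppd["x"])
  aoi$y1 <- min(bounds[4], aoi$y1 + expansion_deg * ppd["y"])
  aoi
}

#' Expand all internal AOIs of a set
#'
#' Applies [expand_aoi()] to every internal AOI (the default 1 degree per
#' side compensates for calibration offsets common in recordings from young
#' children); non-internal AOIs pass through unchanged, silently.
#'
#' @param aois An [aoi_set()].
#' @inheritParams expand_aoi
#' @return The expanded `aoi_set`.
#' @export
expand_aois <- function(aois, expansion_deg = 1, geometry = screen_geometry(),
                        bounds = NULL) {
  if (expansion_deg == 0) return(aois)
  if (is.null(bounds)) bounds <- c(0, 0, geometry$resolution_px)
  ppd <- px_per_degree(geometry)
  dplyr::mutate(
    aois,
    x0 = ifelse(.data$internal, pmax(bounds[1], .data$x0 - expansion_deg * ppd["x"]), .data$x0),
    y0 = ifelse(.data$internal, pmax(bounds[2], .data$y0 - expansion_deg * ppd["y"]), .data$y0),
    x1 = ifelse(.data$internal, pmin(bounds[3], .data$x1 + expansion_deg * ppd["x"]), .data$x1),
    y1 = ifelse(.data$internal, pmin(bounds[4], .data$y1 + expansion_deg * ppd["y"]), .data$y1)
  )
}

# label one point against the (already expanded) AOIs of one stimulus.
# Internal AOIs take precedence over `outer`; overlaps created by expansion
# are resolved by nearest AOI centre, ties by canonical order.
assign_point <- function(px, py, stim_aois) {
  inside <- px >= stim_aois$x0 & px <= stim_aois$x1 &
    py >= stim_aois$y0 & py <= stim_aois$y1
  cand <- stim_aois[inside & stim_aois$internal, ]
  if (nrow(cand) == 0) cand <- stim_aois[inside & !stim_aois$internal, ]
  if (nrow(cand) == 0) return("outside")
  if (nrow(cand) == 1) return(cand$aoi)
  d2 <- (px - (cand$x0 + cand$x1) / 2)^2 + (py - (cand$y0 + cand$y1) / 2)^2
  ord <- match(cand$aoi, AOI_NAMES) # canonical order breaks ties
  cand$aoi[order(d2, ord)][1]
}

#' Assign a fixation centroid to an AOI label
#'
#' @param cx,cy Centroid coordinates in stimulus pixels (vectors allowed).
#' @param aois An expanded [aoi_set()] for a single stimulus (or with a
#'   single distinct stimulus).
#' @return Character vector of labels from
#'   `left_eye, right_eye, nose, mouth, outer, outside`.
#' @export
assign_fixation <- function(cx, cy, aois) {
  if (length(unique(aois$stimulus)) > 1) {
    abort("assign_fixation() expects AOIs for a single stimulus; use label_fixations() for cohorts.",
          class = "gazenet_config_error")
  }
  vapply(seq_along(cx), function(i) assign_point(cx[i], cy[i], aois),
         character(1))
}

#' Label a fixation table with AOI membership
#'
#' Expands the internal AOIs by `expansion_deg`, then assigns every fixation
#' centroid to one of the six labels (five AOIs plus `outside`), preserving
#' trial order. Fixations whose stimulus has no AOI record fall back to the
#' set's `"default"` stimulus if present, or to a single shared layout if the
#' set defines only one stimulus.
#'
#' @param fixations Fixation tibble from [detect_fixations()] (columns
#'   `participant, stimulus, cx, cy`, time-ordered within trials).
#' @param aois An [aoi_set()] (unexpanded).
#' @param expansion_deg Expansion applied to internal AOIs, degrees per side.
#' @param geometry A [screen_geometry()].
#' @return The fixation tibble with an `aoi` factor column (six levels).
#' @export
label_fixations <- function(fixations, aois, expansion_deg = 1,
                            geometry = screen_geometry()) {
  expanded <- expand_aois(aois, expansion_deg, geometry)
  split_aois <- split(expanded, expanded$stimulus)
  fallback <- if ("default" %in% names(split_aois)) {
    split_aois[["default"]]
  } else if (length(split_aois) == 1) {
    split_aois[[1]]
  } else NULL
  lab <- vapply(seq_len(nrow(fixations)), function(i) {
    sa <- split_aois[[fixations$stimulus[i]]]
    if (is.null(sa)) sa <- fallback
    if (is.null(sa)) {
      abort(paste0("No AOI definition for stimulus '", fixations$stimulus[i], "'."),
            class = "gazenet_data_error")
    }
    assign_point(fixations$cx[i], fixations$cy[i], sa)
  }, character(1))
  dplyr::mutate(fixations, aoi = factor(lab, levels = ALL_LABELS))
}

#' Read / write AOI definitions as JSON
#'
#' The sidecar format is a JSON array with one record per stimulus:
#' `{"stimulus": "1", "aois": [{"name": "left_eye", "x0": ..., "y0": ...,
#' "x1": ..., "y1": ..., "internal": true}, ...]}`.
#'
#' @param path File path.
#' @return `read_aoi_json()` returns an [aoi_set()];
#'   `write_aoi_json()` returns `path` invisibly.
#' @export
read_aoi_json <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("AOI file not found: ", path), class = "gazenet_io_error")
  }
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rows <- purrr::map2_dfr(recs$stimulus, recs$aois, function(stim, df) {
    tibble::tibble(stimulus = as.character(stim), aoi = df$name,
                   x0 = df$x0, y0 = df$y0, x1 = df$x1, y1 = df$y1,
                   internal = df$internal)
  })
  aoi_set(rows)
}

#' @rdname read_aoi_json
#' @param aois An [aoi_set()] to serialise.
#' @export
write_aoi_json <- function(aois, path) {
  recs <- aois |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::group_map(function(df, key) {
      list(stimulus = key$stimulus,
           aois = data.frame(name = df$aoi, x0 = df$x0, y0 = df$y0,
                             x1 = df$x1, y1 = df$y1, internal = df$internal))
    })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
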