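#' Read a raw gaze sample table
#'
#' Reads delimited text (CSV or TSV, auto-detected from the extension unless
#' `delim` is given) holding timestamped binocular gaze samples, one row per
#' sample. The documented dialect has columns
#' `participant, stimulus, t_ms, xl, yl, xr, yr, vl, vr`:
#' trial-relative time in milliseconds, left/right eye screen coordinates in
#' pixels (origin top-left, y downward), and per-eye validity flags (0/1 or
#' logical). Other column names can be adapted through `col_map`.
#'
#' Rows with unparseable numeric fields are dropped with a warning naming the
#' row numbers. Timestamps must be strictly increasing within each
#' (participant, stimulus) trial.
#'
#' @param path Path to the delimited file.
#' @param col_map Named character vector mapping the canonical names to the
#'   file's actual column names, e.g. `c(t_ms = "RecTime")`. Unmapped
#'   canonical names are looked up as-is.
#' @param delim Field delimiter; `NULL` means infer from the file extension
#'   (`.tsv`/`.tab` tab, otherwise comma).
#' @return A tibble of gaze samples sorted by participant, stimulus, time,
#'   with canonical column names and types (`vl`/`vr` logical).
#' @seealso [write_gaze_table()], [combine_eyes()]
#' @export
read_gaze_table <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Gaze file not found: ", path), class = "gazenet_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  canonical <- c("participant", "stimulus", "t_ms", "xl", "yl", "xr", "yr", "vl", "vr")
  lookup <- setNames(canonical, canonical)
  if (!is.null(col_map)) lookup[names(col_map)] <- unname(col_map)
  missing <- canonical[!lookup %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("Gaze table is missing required column(s): ",
                 paste(lookup[missing], collapse = ", ")),
          class = "gazenet_format_error")
  }
  gaze <- tibble::as_tibble(raw[, unname(lookup)])
  names(gaze) <- canonical
  gaze <- dplyr::mutate(
    gaze,
    participant = as.character(.data$participant),
    stimulus = as.character(.data$stimulus),
    dplyr::across(c("t_ms", "xl", "yl", "xr", "yr"), as.numeric),
    vl = as.logical(as.integer(.data$vl)),
    vr = as.logical(as.integer(.data$vr))
  )
  bad <- which(is.na(gaze$t_ms) | is.na(gaze$participant) | is.na(gaze$stimulus) |
                 is.na(gaze$vl) | is.na(gaze$vr))
  if (length(bad) > 0) {
    warn(paste0("Dropped ", length(bad), " malformed row(s): ",
                paste(head(bad, 10), collapse = ", "),
                if (length(bad) > 10) ", ..." else ""))
    gaze <- gaze[-bad, ]
  }
  validate_gaze(gaze)
  dplyr::arrange(gaze, .data$participant, .data$stimulus, .data$t_ms)
}

#' Validate a gaze sample tibble
#'
#' Checks the invariants every downstream stage assumes: canonical columns
#' present and timestamps strictly increasing within each trial.
#'
#' @param gaze A gaze sample tibble as returned by [read_gaze_table()].
#' @return `gaze`, invisibly, if valid; otherwise an error.
#' @export
validate_gaze <- function(gaze) {
  canonical <- c("participant", "stimulus", "t_ms", "xl", "yl", "xr", "yr", "vl", "vr")
  missing <- setdiff(canonical, names(gaze))
  if (length(missing) > 0) {
    abort(paste0("Gaze table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gazenet_format_error")
  }
  nonmono <- gaze |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::summarise(ok = all(diff(.data$t_ms) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(nonmono) > 0) {
    abort(paste0("Non-monotone timestamps in trial(s): ",
                 paste(paste0(nonmono$participant, "/", nonmono$stimulus),
                       collapse = ", ")),
          class = "gazenet_data_error")
  }
  invisible(gaze)
}

#' Write a gaze sample table
#'
#' Inverse of [read_gaze_table()]: writes the canonical CSV dialect with
#' validity flags as 0/1 integers.
#'
#' @param gaze Gaze sample tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(gaze, path) {
  out <- dplyr::mutate(gaze, vl = as.integer(.data$vl), vr = as.integer(.data$vr))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Combine the two eyes into one gaze position
#'
#' Adds cyclopean columns `x`, `y`, `valid` to a gaze tibble. When both eyes
#' are valid the coordinate is their arithmetic mean; when only one is valid
#' that eye is used; when neither is valid the sample is invalid and its
#' coordinates are `NA`. The averaging rule is a convention (recording is
#' binocular, but no combination rule is implied by the hardware); `rule`
#' selects a single-eye alternative.
#'
#' @param gaze Gaze sample tibble with `xl, yl, xr, yr, vl, vr`.
#' @param rule `"mean"` (default), `"left"` or `"right"`.
#' @return The input tibble with `x`, `y`, `valid` columns appended.
#' @export
combine_eyes <- function(gaze, rule = c("mean", "left", "right")) {
  rule <- match.arg(rule)
  switch(rule,
    mean = dplyr::mutate(
      gaze,
      valid = .data$vl | .data$vr,
      x = dplyr::case_when(
        .data$vl & .data$vr ~ (.data$xl + .data$xr) / 2,
        .data$vl ~ .data$xl,
        .data$vr ~ .data$xr,
        TRUE ~ NA_real_
      ),
      y = dplyr::case_when(
        .data$vl & .data$vr ~ (.data$yl + .data$yr) / 2,
        .data$vl ~ .data$yl,
        .data$vr ~ .data$yr,
        TRUE ~ NA_real_
      )
    ),
    left = dplyr::mutate(gaze, valid = .data$vl,
                         x = ifelse(.data$vl, .data$xl, NA_real_),
                         y = ifelse(.data$vl, .data$yl, NA_real_)),
    right = dplyr::mutate(gaze, valid = .data$vr,
                          x = ifelse(.data$vr, .data$xr, NA_real_),
                          y = ifelse(.data$vr, .data$yr, NA_real_))
  )
}

#' Read a participant metadata table
#'
#' CSV with columns `id, group, ca_months, nvma_months, vma_months, sex`.
#' `group` must take exactly two distinct labels across the file (the design
#' is a two-group comparison).
#'
#' @param path Path to the CSV file.
#' @return A tibble with `group` as a factor.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Metadata file not found: ", path), class = "gazenet_io_error")
  }
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "group", "ca_months", "nvma_months", "vma_months", "sex")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gazenet_format_error")
  }
  meta <- dplyr::mutate(meta, id = as.character(.data$id),
                        group = factor(.data$group))
  if (nlevels(meta$group) != 2) {
    abort("Metadata `group` must have exactly two levels.",
          class = "gazenet_data_error")
  }
  ages <- c("ca_months", "nvma_months", "vma_months")
  if (any(as.matrix(meta[ages]) <= 0, na.rm = TRUE)) {
    abort("Ages in months must be positive.", class = "gazenet_data_error")
  }
  meta
}

#' Read a per-participant supplementary summary table (XLSX)
#'
#' Reads an individual-data workbook of per-participant outcome summaries
#' (one row per participant; at minimum an id, a group column and left/right
#' eye fixation-time percentages). The exact layout of such supplements
#' varies, so the reader takes the sheet and a column map rather than
#' guessing.
#'
#' @param path Path to the `.xlsx` file.
#' @param sheet Sheet name or index passed to `readxl::read_excel()`.
#' @param col_map Named character vector mapping canonical names
#'   (`id, group, pct_left_eye, pct_right_eye, ...`) to workbook columns.
#' @return A tibble with the mapped canonical columns.
#' @export
read_s1_table <- function(path, sheet = 1, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Supplementary table not found: ", path),
          class = "gazenet_io_error")
  }
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("Package 'readxl' is required to read XLSX supplements.",
          class = "gazenet_config_error")
  }
  raw <- readxl::read_excel(path, sheet = sheet)
  if (is.null(col_map)) return(tibble::as_tibble(raw))
  missing <- col_map[!col_map %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("Supplement is missing mapped column(s): ",
                 paste(missing, collapse = ", ")),
          class = "gazenet_format_error")
  }
  out <- tibble::as_tibble(raw[, unname(col_map)])
  names(out) <- names(col_map)
  out
}

#' Write the result bundle to CSV files
#'
#' Writes each table of a pipeline result bundle (fixations, per-participant
#' fixation-time metrics, transition matrices in long form, centrality table,
#' group-statistics summary) as a CSV with stable column order, plus the JSON
#' summary.
#'
#' @param results A `gaze_results` bundle from [run_pipeline()], or a named
#'   list of data frames.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("Cannot create output directory: ", out_dir),
          class = "gazenet_io_error")
  }
  tables <- if (inherits(results, "gaze_results")) results$tables else results
  stopifnot(is.list(tables), !is.null(names(tables)))
  files <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, f, progress = FALSE)
    files[nm] <- f
  }
  if (inherits(results, "gaze_results") && !is.null(results$summary)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(results$summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files["summary"] <- f
  }
  inform(paste0("Wrote ", length(files), " file(s) to ", out_dir))
  invisible(files)
}
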