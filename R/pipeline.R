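#' Pipeline configuration
#'
#' Collects the file paths and analysis options for a full run. Every
#' study constant is a named default here — the 35 deg/s velocity
#' threshold and 100 ms minimum duration (in `detection`), the 1 degree AOI
#' expansion, the 0.50 no-bias ratio reference — never hard-coded inline in
#' the stages.
#'
#' @param gaze_path,aoi_path,metadata_path Input files (canonical gaze CSV,
#'   AOI JSON sidecar, metadata CSV). Validated to exist immediately.
#' @param out_dir Optional output directory; when given, [run_pipeline()]
#'   writes the CSV bundle there.
#' @param detection A [detection_config()].
#' @param geometry A [screen_geometry()].
#' @param expansion_deg AOI expansion per side, degrees.
#' @param percent_method `"per_trial"` or `"pooled"` (see
#'   [fixation_time_percent()]).
#' @param bridge_outside Bridge single outside fixations when counting
#'   transitions (see [build_transition_matrix()]).
#' @param ratio_mu Reference value for the left/right ratio t-tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gaze_path, aoi_path, metadata_path,
                            out_dir = NULL,
                            detection = detection_config(),
                            geometry = screen_geometry(),
                            expansion_deg = 1,
                            percent_method = c("per_trial", "pooled"),
                            bridge_outside = FALSE,
                            ratio_mu = 0.50) {
  percent_method <- match.arg(percent_method)
  for (p in c(gaze_path, aoi_path, metadata_path)) {
    if (!file.exists(p)) {
      abort(paste0("Configured input does not exist: ", p),
            class = "gazenet_config_error")
    }
  }
  structure(
    list(gaze_path = gaze_path, aoi_path = aoi_path,
         metadata_path = metadata_path, out_dir = out_dir,
         detection = detection, geometry = geometry,
         expansion_deg = expansion_deg, percent_method = percent_method,
         bridge_outside = bridge_outside, ratio_mu = ratio_mu),
    class = "pipeline_config"
  )
}

#' Analyse a cohort end to end
#'
#' The in-memory pipeline: fixation detection, AOI labeling, fixation-time
#' metrics, transition networks with standardized weighted degree
#' centrality, and the group-level statistics (ANCOVAs in both covariate
#' model variants, ratio t-tests, per-AOI correlation comparison). The
#' whole computation is deterministic in its inputs.
#'
#' @param gaze Raw gaze sample tibble (canonical columns), or `NULL` if
#'   `fixations` is supplied directly.
#' @param aois An [aoi_set()].
#' @param metadata Participant metadata tibble (`id, group, ca_months,
#'   nvma_months, vma_months, sex`).
#' @param fixations Optional pre-detected fixation tibble (e.g. a synthetic
#'   plan); bypasses detection.
#' @inheritParams pipeline_config
#' @return A `gaze_results` bundle: `$tables` (fixations, metrics,
#'   transitions, centrality, group_stats, ratio_tests,
#'   correlation_comparison, group_means), `$summary` (list mirroring the
#'   tables for JSON export), `$exclusions`.
#' @export
analyze_cohort <- function(gaze, aois, metadata,
                           fixations = NULL,
                           detection = detection_config(),
                           geometry = screen_geometry(),
                           expansion_deg = 1,
                           percent_method = "per_trial",
                           bridge_outside = FALSE,
                           ratio_mu = 0.50) {
  metadata <- dplyr::mutate(metadata, id = as.character(.data$id),
                            group = factor(.data$group))
  if (is.null(fixations)) {
    fixations <- detect_fixations(gaze, detection, geometry)
  }
  labeled <- if ("aoi" %in% names(fixations)) {
    # already-labeled fixations (e.g. a synthetic plan) bypass AOI assignment
    dplyr::mutate(fixations, aoi = factor(.data$aoi, levels = ALL_LABELS))
  } else {
    label_fixations(fixations, aois, expansion_deg, geometry)
  }
  metrics <- fixation_metrics(labeled, percent_method)
  centrality <- aoi_centrality(labeled, bridge_outside = bridge_outside)

  exclusions <- metadata |>
    dplyr::filter(!.data$id %in% metrics$participant) |>
    dplyr::transmute(participant = .data$id,
                     reason = "no fixation time in any trial")
  no_ratio <- metrics$participant[is.na(metrics$lr_ratio)]
  if (length(no_ratio) > 0) {
    exclusions <- dplyr::bind_rows(
      exclusions,
      tibble::tibble(participant = no_ratio,
                     reason = "no eye-region fixation time (ratio undefined)"))
  }

  merged <- metrics |>
    dplyr::inner_join(dplyr::rename(metadata, participant = "id"),
                      by = "participant")
  cent_wide <- centrality |>
    dplyr::select("participant", "aoi", "c_dw") |>
    tidyr::pivot_wider(names_from = "aoi", values_from = "c_dw",
                       names_prefix = "cdw_")
  merged <- dplyr::inner_join(merged, cent_wide, by = "participant")

  outcomes <- c(paste0("pct_", AOI_NAMES), paste0("cdw_", AOI_NAMES), "lr_ratio")
  group_stats <- purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(c(TRUE, FALSE), function(inter) {
      fit <- tryCatch(
        ancova_group_effect(merged, oc, group = "group",
                            covariates = c("vma_months", "nvma_months"),
                            include_interactions = inter),
        error = function(e) NULL)
      if (is.null(fit)) return(tibble::tibble())
      dplyr::mutate(tidy(fit), model = ifelse(inter, "interactions",
                                              "covariates_only"),
                    .after = "outcome")
    })
  })

  lv <- levels(metadata$group)
  ratio_tests <- purrr::map_dfr(lv, function(g) {
    vals <- merged$lr_ratio[merged$group == g]
    dplyr::mutate(one_sample_t(vals, mu = ratio_mu), group = g, .before = 1)
  })

  group_means <- merged |>
    tidyr::pivot_longer(dplyr::all_of(c(paste0("pct_", AOI_NAMES),
                                        paste0("cdw_", AOI_NAMES),
                                        "lr_ratio", "total_fix_s")),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")

  cor_cmp <- compare_aoi_correlations(metrics, centrality, metadata)

  summary <- list(
    n_participants = nrow(metadata),
    n_analysed = nrow(merged),
    groups = as.list(table(metadata$group)),
    group_means = group_means,
    ratio = list(mu = ratio_mu, tests = ratio_tests),
    correlation_comparison = cor_cmp,
    note = "p-values are not corrected for multiple comparisons"
  )

  structure(
    list(tables = list(
           fixations = labeled,
           metrics = metrics,
           transitions = transition_counts(labeled,
                                           bridge_outside = bridge_outside),
           centrality = centrality,
           group_stats = group_stats,
           ratio_tests = ratio_tests,
           group_means = group_means,
           correlation_comparison = cor_cmp),
         summary = summary,
         exclusions = exclusions,
         options = list(expansion_deg = expansion_deg,
                        percent_method = percent_method,
                        bridge_outside = bridge_outside,
                        ratio_mu = ratio_mu,
                        detection = unclass(detection))),
    class = "gaze_results"
  )
}

#' @export
print.gaze_results <- function(x, ...) {
  cat(sprintf("<gaze_results> %d participants analysed, %d excluded; tables: %s\n",
              x$summary$n_analysed, nrow(x$exclusions),
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Run the full file-to-file pipeline
#'
#' Reads the configured inputs, runs [analyze_cohort()], and (when the
#' config names an output directory) writes the CSV bundle, the JSON
#' summary, and the exclusion log. Identical inputs and config produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The `gaze_results` bundle, invisibly when writing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gaze <- read_gaze_table(config$gaze_path)
  aois <- read_aoi_json(config$aoi_path)
  metadata <- read_metadata(config$metadata_path)
  results <- analyze_cohort(
    gaze, aois, metadata,
    detection = config$detection, geometry = config$geometry,
    expansion_deg = config$expansion_deg,
    percent_method = config$percent_method,
    bridge_outside = config$bridge_outside, ratio_mu = config$ratio_mu)
  if (!is.null(config$out_dir)) {
    write_results(results, config$out_dir)
    if (nrow(results$exclusions) > 0) {
      readr::write_csv(results$exclusions,
                       file.path(config$out_dir, "exclusions.csv"),
                       progress = FALSE)
    }
    return(invisible(results))
  }
  results
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a Markdown report from a result bundle
#'
#' Produces a human-readable report with the cohort description, the
#' per-AOI group means of fixation time and centrality, the left/right
#' ratio analysis and the correlation comparison — the standard summary
#' tables of a face-scanning group study — with the uncorrected-p caveat
#' stated.
#'
#' @param results A `gaze_results` bundle.
#' @param path Optional file to write the Markdown to.
#' @return The report as a single character string (invisibly if written).
#' @export
make_report <- function(results, path = NULL) {
  if (!inherits(results, "gaze_results")) {
    abort("make_report() expects a gaze_results bundle.",
          class = "gazenet_config_error")
  }
  needed <- c("metrics", "centrality", "group_means", "ratio_tests",
              "correlation_comparison")
  missing <- needed[!vapply(needed, function(nm)
    !is.null(results$tables[[nm]]) && nrow(results$tables[[nm]]) > 0,
    logical(1))]
  if (length(missing) > 0) {
    abort(paste0("Result bundle is incomplete; missing table(s): ",
                 paste(missing, collapse = ", ")),
          class = "gazenet_data_error")
  }
  gm <- results$tables$group_means
  pct <- gm[grepl("^pct_", gm$measure), ]
  cdw <- gm[grepl("^cdw_", gm$measure), ]
  parts <- c(
    "# Face-scanning analysis report",
    "",
    sprintf("Participants analysed: %d of %d (%d excluded).",
            results$summary$n_analysed, results$summary$n_participants,
            nrow(results$exclusions)),
    "",
    "## Fixation time by AOI (percent of total fixation time)",
    "",
    md_table(tidyr::pivot_wider(pct, names_from = "group",
                                values_from = c("mean", "sd"),
                                id_cols = "measure")),
    "",
    "## Standardized weighted degree centrality by AOI (0-100)",
    "",
    md_table(tidyr::pivot_wider(cdw, names_from = "group",
                                values_from = c("mean", "sd"),
                                id_cols = "measure")),
    "",
    sprintf("## Left/right eye ratio (reference %.2f)", results$options$ratio_mu),
    "",
    md_table(results$tables$ratio_tests),
    "",
    "## Fixation time vs. centrality: correlations and group comparison",
    "",
    md_table(results$tables$correlation_comparison),
    "",
    "*p-values are not corrected for multiple comparisons.*",
    ""
  )
  report <- paste(parts, collapse = "\n")
  if (!is.null(path)) {
    writeLines(report, path)
    return(invisible(report))
  }
  report
}
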