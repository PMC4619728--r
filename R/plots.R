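#' Plot per-AOI fixation-time percentages by group
#'
#' @param metrics Per-participant metrics table from [fixation_metrics()].
#' @param metadata Participant metadata (`id`, `group`).
#' @return A ggplot: boxplots of per-AOI percentage by group.
#' @export
plot_fixation_times <- function(metrics, metadata) {
  long <- metrics |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "aoi",
                        values_to = "pct", names_prefix = "pct_") |>
    dplyr::inner_join(dplyr::select(metadata, participant = "id", "group"),
                      by = "participant") |>
    dplyr::mutate(aoi = factor(.data$aoi, levels = ALL_LABELS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$aoi, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, position = "dodge") +
    ggplot2::labs(x = "AOI", y = "% of total fixation time", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot standardized weighted degree centrality by group
#'
#' @param centrality Cohort centrality table from [aoi_centrality()].
#' @param metadata Participant metadata (`id`, `group`).
#' @return A ggplot: boxplots of per-AOI centrality by group.
#' @export
plot_centrality <- function(centrality, metadata) {
  df <- centrality |>
    dplyr::inner_join(dplyr::select(metadata, participant = "id", "group"),
                      by = "participant") |>
    dplyr::mutate(aoi = factor(.data$aoi, levels = AOI_NAMES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aoi, y = .data$c_dw,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, position = "dodge") +
    ggplot2::labs(x = "AOI", y = "Standardized weighted degree centrality (0-100)",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot an AOI transition network
#'
#' Draws the weighted undirected network of a transition matrix with nodes
#' on a circle, edge width proportional to the pair's transition count and
#' node size to its strength.
#'
#' @param counts Transition count matrix from [build_transition_matrix()]
#'   (or an already-symmetric adjacency).
#' @return A ggplot.
#' @export
plot_transition_network <- function(counts) {
  w <- to_weighted_adjacency(counts)
  nm <- rownames(w) %||% as.character(seq_len(nrow(w)))
  k <- nrow(w)
  theta <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  nodes <- tibble::tibble(aoi = nm, x = cos(theta), y = sin(theta),
                          strength = node_strength(w),
                          c_dw = weighted_degree_centrality(w))
  pairs <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    x = nodes$x[pairs[, 1]], y = nodes$y[pairs[, 1]],
    xend = nodes$x[pairs[, 2]], yend = nodes$y[pairs[, 2]],
    weight = w[pairs]
  )
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey55", show.legend = FALSE)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$strength),
                        colour = "steelblue", show.legend = FALSE) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.22 * .data$x, y = 1.22 * .data$y,
                                    label = sprintf("%s\nC_Dw = %.0f",
                                                    .data$aoi, .data$c_dw)),
                       size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6)) +
    ggplot2::theme_void()
}

#' Autoplot a pipeline result bundle
#'
#' @param object A `gaze_results` bundle.
#' @param which `"centrality"` (default) or `"fixation_time"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gaze_results
#' @export
autoplot.gaze_results <- function(object, which = c("centrality", "fixation_time"),
                                  ...) {
  which <- match.arg(which)
  gm <- object$tables$group_means
  prefix <- if (which == "centrality") "cdw_" else "pct_"
  df <- gm[grepl(paste0("^", prefix), gm$measure), ] |>
    dplyr::mutate(aoi = factor(sub(prefix, "", .data$measure),
                               levels = ALL_LABELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aoi, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(
      x = "AOI",
      y = if (which == "centrality")
        "Standardized weighted degree centrality (0-100)"
      else "% of total fixation time",
      fill = "Group") +
    ggplot2::theme_minimal()
}
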