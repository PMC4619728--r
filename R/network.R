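#' Build a participant's AOI transition matrix
#'
#' A transition is a saccade from one face AOI directly to a *different*
#' face AOI: for every pair of consecutive fixations within a trial whose
#' labels are two distinct AOIs of the five-AOI set, the cell
#' (departure, arrival) is incremented. Consecutive fixations in the same
#' AOI are not transitions, pairs involving `outside` contribute nothing
#' (unless `bridge_outside = TRUE`, which lets a single intervening
#' `outside` fixation be skipped), and counts never cross trial boundaries.
#' All of a participant's trials accumulate into one matrix.
#'
#' @param labeled Labeled fixation tibble for one participant (or a list of
#'   per-trial label vectors). Rows must be time-ordered within trials.
#' @param aoi_names Ordered AOI names giving the matrix dimensions.
#' @param bridge_outside If `TRUE`, a single `outside` fixation between two
#'   AOI fixations is bridged (AOI -> outside -> AOI counts as one
#'   transition). Default `FALSE`: only directly consecutive AOI fixations
#'   count.
#' @return An N x N integer matrix, rows = departure AOI, columns = arrival
#'   AOI, zero diagonal, dimnames `aoi_names`.
#' @examples
#' build_transition_matrix(list(c("left_eye", "left_eye", "nose", "mouth")))
#' @export
build_transition_matrix <- function(labeled, aoi_names = AOI_NAMES,
                                    bridge_outside = FALSE) {
  if (is.data.frame(labeled)) {
    if ("participant" %in% names(labeled) &&
        length(unique(labeled$participant)) > 1) {
      abort("build_transition_matrix() takes one participant; use aoi_centrality() for cohorts.",
            class = "gazenet_config_error")
    }
    seqs <- split(as.character(labeled$aoi), labeled$stimulus)
  } else {
    seqs <- lapply(labeled, as.character)
  }
  counts <- matrix(0L, length(aoi_names), length(aoi_names),
                   dimnames = list(aoi_names, aoi_names))
  if (bridge_outside) {
    seqs <- lapply(seqs, function(labs) {
      if (length(labs) <= 2) return(labs)
      # drop single outside fixations flanked by AOI fixations
      mid <- 2:(length(labs) - 1)
      drop <- labs[mid] == "outside" & labs[mid - 1] %in% aoi_names &
        labs[mid + 1] %in% aoi_names
      if (any(drop)) labs[-mid[drop]] else labs
    })
  }
  # pool consecutive pairs across trials; a sentinel label between trials
  # prevents pairs from spanning a trial boundary
  labs <- unlist(lapply(unname(seqs), function(s) c(s, NA_character_)),
                 use.names = FALSE)
  if (length(labs) >= 2) {
    from <- labs[-length(labs)]
    to <- labs[-1]
    ok <- !is.na(from) & !is.na(to) & from %in% aoi_names &
      to %in% aoi_names & from != to
    if (any(ok)) {
      counts <- counts + unclass(table(factor(from[ok], aoi_names),
                                       factor(to[ok], aoi_names)))
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Collapse a transition matrix to a weighted undirected adjacency matrix
#'
#' Direction is discarded: the weight of the pair (i, j) is the total number
#' of transitions between the two AOIs in either direction,
#' `counts[i, j] + counts[j, i]`. The result is symmetric with a zero
#' diagonal.
#'
#' @param counts Square transition count matrix (rows departure, columns
#'   arrival).
#' @return Symmetric integer weight matrix of the same dimension.
#' @export
to_weighted_adjacency <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  w <- counts + t(counts)
  diag(w) <- 0
  storage.mode(w) <- storage.mode(counts)
  w
}

#' Degree centrality of each AOI node
#'
#' The number of distinct other nodes a node is directly connected to:
#' the row sums of the binarized adjacency matrix. Ranges from 0 to N - 1.
#'
#' @param adjacency Symmetric weight matrix from [to_weighted_adjacency()].
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(adjacency) {
  stopifnot(is.matrix(adjacency), isTRUE(all.equal(adjacency, t(adjacency))))
  d <- rowSums(adjacency > 0)
  storage.mode(d) <- "integer"
  d
}

#' Node strength: total transitions involving each AOI
#'
#' The weighted row sums of the adjacency matrix — the total number of
#' transitions (links) attached to the node.
#'
#' @inheritParams degree_centrality
#' @return Named integer vector of strengths.
#' @export
node_strength <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  s <- rowSums(adjacency)
  storage.mode(s) <- "integer"
  s
}

#' Standardized weighted degree centrality (0-100)
#'
#' The network measure at the heart of this package: for node i,
#' \deqn{C_D^w(i) = \frac{C_D(i)}{\max C_D} \times \frac{w(i)}{\max w} \times 100}
#' where \eqn{C_D(i)} is the degree (number of directly connected AOIs),
#' \eqn{w(i)} the strength (total transitions involving the AOI), and the
#' maxima are taken across the nodes of the same network. The measure
#' weighs how many other features an AOI exchanges gaze with and how often,
#' equally and without a tuning parameter, and is standardized within each
#' participant's network so values are comparable across participants. It
#' ranges from 0 to 100; the node attaining both within-network maxima
#' scores exactly 100. In an empty network (no transitions) all values are
#' defined as 0 rather than erroring, so low-data participants flow through
#' cohort pipelines and can be flagged downstream.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of centralities in `[0, 100]`.
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
#' w["a", "b"] <- w["b", "a"] <- 4
#' w["a", "c"] <- w["c", "a"] <- 1
#' weighted_degree_centrality(w) # a = 100, b = 40, c = 10
#' @export
weighted_degree_centrality <- function(adjacency) {
  cd <- degree_centrality(adjacency)
  w <- node_strength(adjacency)
  if (max(cd) == 0L || max(w) == 0L) {
    return(setNames(numeric(length(cd)), names(cd)))
  }
  (cd / max(cd)) * (w / max(w)) * 100
}

#' Per-AOI centrality table for one network
#'
#' @inheritParams degree_centrality
#' @return Tibble `aoi, c_d, w, c_dw`.
#' @export
centrality_table <- function(adjacency) {
  tibble::tibble(
    aoi = rownames(adjacency) %||% as.character(seq_len(nrow(adjacency))),
    c_d = unname(degree_centrality(adjacency)),
    w = unname(node_strength(adjacency)),
    c_dw = unname(weighted_degree_centrality(adjacency))
  )
}

#' Cohort-level AOI centrality
#'
#' Builds each participant's transition matrix from their labeled fixations,
#' collapses it to a weighted undirected network and computes degree,
#' strength and standardized weighted degree centrality per AOI.
#' Participants whose network is empty (no transitions at all) are kept with
#' zero centralities and flagged in the `empty_network` column.
#'
#' @param labeled Labeled fixation tibble for the whole cohort
#'   (time-ordered within each participant x stimulus trial).
#' @inheritParams build_transition_matrix
#' @return Tibble `participant, aoi, c_d, w, c_dw, n_transitions,
#'   empty_network` with five rows per participant.
#' @export
aoi_centrality <- function(labeled, aoi_names = AOI_NAMES,
                           bridge_outside = FALSE) {
  labeled |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(df, key) {
      counts <- build_transition_matrix(df, aoi_names, bridge_outside)
      adj <- to_weighted_adjacency(counts)
      dplyr::mutate(centrality_table(adj),
                    n_transitions = sum(counts),
                    empty_network = sum(counts) == 0L)
    }) |>
    dplyr::ungroup()
}

#' Long-form transition counts for a cohort
#'
#' One row per participant and ordered AOI pair, suitable for CSV export of
#' the per-participant transition matrices.
#'
#' @inheritParams aoi_centrality
#' @return Tibble `participant, from, to, n`.
#' @export
transition_counts <- function(labeled, aoi_names = AOI_NAMES,
                              bridge_outside = FALSE) {
  labeled |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(df, key) {
      counts <- build_transition_matrix(df, aoi_names, bridge_outside)
      tibble::as_tibble(as.data.frame.table(counts, stringsAsFactors = FALSE)) |>
        setNames(c("from", "to", "n"))
    }) |>
    dplyr::ungroup()
}
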