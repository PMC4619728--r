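# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

aoi5 <- c("left_eye", "right_eye", "nose", "mouth", "outer")

# symmetric adjacency from an edge list over nodes 1..n
adjacency_from_edges <- function(edges, n = 5, weight = 1,
                                 names = as.character(seq_len(n))) {
  w <- matrix(0L, n, n, dimnames = list(names, names))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    w[i, j] <- w[i, j] + weight
    w[j, i] <- w[j, i] + weight
  }
  w
}

# the fictitious worked-example network: edges over nodes 1..5
worked_example_adjacency <- function() {
  adjacency_from_edges(rbind(c(1, 2), c(1, 4), c(1, 5),
                             c(2, 3), c(2, 4), c(3, 4), c(3, 5)))
}

# brute-force reference for degree, strength and standardized weighted
# degree centrality: explicit elementwise loops, no matrix algebra shared
# with the implementation
brute_force_centrality <- function(w) {
  n <- nrow(w)
  cd <- integer(n); s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && w[i, j] > 0) cd[i] <- cd[i] + 1L
      if (j != i) s[i] <- s[i] + w[i, j]
    }
  }
  max_cd <- 0; max_s <- 0
  for (i in seq_len(n)) {
    if (cd[i] > max_cd) max_cd <- cd[i]
    if (s[i] > max_s) max_s <- s[i]
  }
  cdw <- numeric(n)
  if (max_cd > 0 && max_s > 0) {
    for (i in seq_len(n)) cdw[i] <- (cd[i] / max_cd) * (s[i] / max_s) * 100
  }
  list(c_d = cd, w = s, c_dw = cdw)
}

# random symmetric integer-weight network on n nodes
random_adjacency <- function(n = 5, max_w = 10, p_zero = 0.3) {
  w <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (runif(1) < p_zero) 0L else sample.int(max_w, 1)
      w[i, j] <- v; w[j, i] <- v
    }
  }
  dimnames(w) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  w
}

# a stationary-gaze sample stream: one trial at `hz`, both eyes valid
constant_gaze <- function(x, y, duration_ms, hz = 60, participant = "p1",
                          stimulus = "1", t0 = 0) {
  t_ms <- seq(t0, t0 + duration_ms - 1e-9, by = 1000 / hz)
  tibble::tibble(participant = participant, stimulus = stimulus, t_ms = t_ms,
                 xl = x, yl = y, xr = x, yr = y, vl = TRUE, vr = TRUE)
}

# a labeled-fixation tibble from per-trial label/duration specs:
# specs = list(list(labels=, durations=), ...)
labeled_from_specs <- function(specs, participant = "p1") {
  rows <- purrr::imap_dfr(specs, function(sp, s) {
    durs <- sp$durations %||% rep(200, length(sp$labels))
    onset <- cumsum(c(50, head(durs, -1) + 50))
    tibble::tibble(participant = participant, stimulus = as.character(s),
                   onset_ms = onset, offset_ms = onset + durs,
                   duration_ms = durs,
                   aoi = factor(sp$labels,
                                levels = c(aoi5, "outside")))
  })
  rows
}
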