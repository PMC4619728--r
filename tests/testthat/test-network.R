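test_that("transition matrices count only direct different-AOI pairs within trials", {
  # labels 1,1,2,3,3,4 over aoi indices -> cells (1,2), (2,3), (3,4)
  labs <- aoi5[c(1, 1, 2, 3, 3, 4)]
  m <- build_transition_matrix(list(labs))
  expect_identical(sum(m), 3L)
  expect_identical(m["left_eye", "right_eye"], 1L)
  expect_identical(m["right_eye", "nose"], 1L)
  expect_identical(m["nose", "mouth"], 1L)
  expect_true(all(diag(m) == 0))

  # three passes 3->4 and one 3->5 accumulate in the right cells
  seqs <- list(aoi5[c(3, 4, 3, 4, 3, 4, 3, 5)])
  m2 <- build_transition_matrix(seqs)
  expect_identical(m2["nose", "mouth"], 3L)
  expect_identical(m2["nose", "outer"], 1L)

  # empty scanpath gives the zero matrix
  expect_true(all(build_transition_matrix(list(character(0))) == 0))
})

test_that("outside fixations and trial boundaries never produce transitions", {
  labs <- c("left_eye", "outside", "mouth")
  expect_true(all(build_transition_matrix(list(labs)) == 0))
  # bridging recovers the indirect pair as a single transition
  bridged <- build_transition_matrix(list(labs), bridge_outside = TRUE)
  expect_identical(bridged["left_eye", "mouth"], 1L)
  expect_identical(sum(bridged), 1L)
  # last fixation of one trial and first of the next are unrelated
  two_trials <- list("left_eye", "mouth")
  expect_true(all(build_transition_matrix(two_trials) == 0))
})

test_that("direction collapses into symmetric weights with zero diagonal", {
  counts <- matrix(0L, 5, 5, dimnames = list(aoi5, aoi5))
  counts[1, 2] <- 2L; counts[2, 1] <- 3L
  w <- to_weighted_adjacency(counts)
  expect_identical(w[1, 2], 5L)
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(to_weighted_adjacency(counts * 0L) == 0))
  sym <- counts; sym[2, 1] <- 2L
  expect_identical(to_weighted_adjacency(sym)[1, 2], 4L)
})

test_that("degree centrality reproduces the worked five-node example", {
  w <- worked_example_adjacency()
  cd <- degree_centrality(w)
  expect_identical(unname(cd["1"]), 3L)
  expect_identical(unname(cd["5"]), 2L)
  expect_true(all(degree_centrality(w * 0L) == 0))
})

test_that("node strength is the weighted row sum and satisfies the handshake identity", {
  w <- matrix(0L, 5, 5)
  w[1, 2] <- w[2, 1] <- 4L
  w[1, 3] <- w[3, 1] <- 1L
  expect_identical(unname(node_strength(w)[1]), 5L)
  for (s in 1:5) {
    r <- withr::with_seed(s, random_adjacency())
    expect_identical(sum(node_strength(r)), 2L * sum(r[upper.tri(r)]))
  }
})

test_that("standardized weighted degree centrality matches hand evaluation", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 4
  w["a", "c"] <- w["c", "a"] <- 1
  expect_equal(unname(weighted_degree_centrality(w)), c(100, 40, 10))
  # the node attaining both maxima scores exactly 100
  r <- withr::with_seed(7, random_adjacency())
  cdw <- weighted_degree_centrality(r)
  cd <- degree_centrality(r); s <- node_strength(r)
  both <- which(cd == max(cd) & s == max(s))
  if (length(both) > 0) expect_equal(unname(cdw[both]), rep(100, length(both)))
  # empty network: all zero, no error
  expect_identical(unname(weighted_degree_centrality(matrix(0, 5, 5))),
                   rep(0, 5))
})

test_that("centrality is equivariant under AOI relabeling", {
  for (s in 1:10) {
    w <- withr::with_seed(s, random_adjacency())
    p <- withr::with_seed(s + 100, sample(5))
    wp <- w[p, p]
    expect_equal(unname(weighted_degree_centrality(wp)),
                 unname(weighted_degree_centrality(w)[p]), tolerance = 1e-12)
    expect_identical(unname(degree_centrality(wp)),
                     unname(degree_centrality(w)[p]))
  }
})

test_that("implementation agrees with the brute-force oracle and igraph on random networks", {
  skip_if_not_installed("igraph")
  for (s in 1:25) {
    w <- withr::with_seed(s, random_adjacency(max_w = 8))
    bf <- brute_force_centrality(w)
    expect_identical(unname(degree_centrality(w)), bf$c_d)
    expect_equal(unname(node_strength(w)), bf$w, ignore_attr = TRUE)
    expect_equal(unname(weighted_degree_centrality(w)), bf$c_dw,
                 tolerance = 1e-9)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(unname(degree_centrality(w))[as.integer(igraph::V(g))],
                 unname(igraph::degree(g)), ignore_attr = TRUE)
    expect_equal(unname(node_strength(w)),
                 unname(igraph::strength(g)), ignore_attr = TRUE)
  }
})

test_that("total transition count is conserved from the labeled scanpaths", {
  co <- generate_cohort(cohort_design(n_per_group = c(4, 4)), seed = 53)
  cen <- aoi_centrality(co$plans)
  # direct count: consecutive same-trial pairs with two distinct face AOIs
  direct <- co$plans |>
    dplyr::group_by(participant, stimulus) |>
    dplyr::summarise(
      k = {
        l <- as.character(aoi)
        from <- head(l, -1); to <- tail(l, -1)
        sum(from %in% aoi5 & to %in% aoi5 & from != to)
      }, .groups = "drop") |>
    dplyr::group_by(participant) |>
    dplyr::summarise(k = sum(k))
  got <- dplyr::distinct(cen, participant, n_transitions)
  expect_identical(got$n_transitions[match(direct$participant, got$participant)],
                   as.integer(direct$k))
  # strengths sum to twice the transition total for every participant
  str_tot <- cen |>
    dplyr::group_by(participant) |>
    dplyr::summarise(s = sum(w))
  expect_identical(as.integer(str_tot$s), 2L * as.integer(direct$k))
})
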