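test_that("cosine similarity reproduces hand-computed values", {
  recs <- dplyr::bind_rows(
    make_diary(c("p1", "p2"), "A"),
    make_diary(c("p2", "p3"), "B"),
    make_diary(c("p1", "p2"), "C"),
    make_diary(c("p4", "p5"), "D")
  )
  sim <- cosine_similarity(build_incidence(recs, "high_swb", "weekday"))
  expect_equal(sim["A", "C"], 1)          # identical participant sets
  expect_equal(sim["A", "D"], 0)          # disjoint participant sets
  expect_equal(sim["A", "B"], 1 / sqrt(2 * 2)) # overlap {p2}: 1/sqrt(4) = 0.5
  expect_equal(diag(sim), rep(0, 4), ignore_attr = TRUE)
})

test_that("cosine similarity matches a brute-force double loop", {
  withr::local_seed(123)
  for (rep in 1:20) {
    n_p <- sample(3:6, 1)
    n_a <- sample(2:6, 1)
    m <- matrix(rbinom(n_p * n_a, 1, 0.6), n_p, n_a)
    # guarantee no zero column (zero-participant activities cannot occur)
    empty <- colSums(m) == 0
    m[1, empty] <- 1
    colnames(m) <- sprintf("a%d", seq_len(n_a))
    rownames(m) <- sprintf("p%d", seq_len(n_p))
    inc <- structure(
      list(binary = m, weights = m * 30, persons = rownames(m),
           activities = colnames(m), group_label = "high_swb",
           day_type = "weekday", empty = FALSE),
      class = "incidence_matrix"
    )
    for (w in c("binary", "minutes")) {
      sim <- cosine_similarity(inc, weighting = w)
      ref <- oracle_cosine(if (w == "binary") m else m * 30)
      expect_lt(max(abs(sim - ref)), 1e-12)
      expect_lt(max(abs(sim - t(sim))), 1e-12)
      expect_true(all(sim >= 0 & sim <= 1 + 1e-12))
    }
    # column order must not matter
    perm <- sample(n_a)
    inc2 <- inc
    inc2$binary <- m[, perm, drop = FALSE]
    inc2$weights <- inc$weights[, perm, drop = FALSE]
    inc2$activities <- inc$activities[perm]
    sim2 <- cosine_similarity(inc2)
    sim1 <- cosine_similarity(inc)
    expect_lt(max(abs(sim2[colnames(sim1), colnames(sim1)] - sim1)), 1e-12)
  }
})

test_that("projection keeps exactly the pairs at or above the threshold", {
  recs <- dplyr::bind_rows(
    make_diary(c("p1", "p2"), "A"),
    make_diary(c("p2", "p3"), "B"),   # sim(A,B) = 0.5
    make_diary(c("p4", "p5"), "C")    # disjoint from both
  )
  inc <- build_incidence(recs, "high_swb", "weekday")
  net <- project_network(inc, tau = 0.3)
  edges <- tidy(net)
  expect_equal(nrow(edges), 1L)
  expect_equal(sort(c(edges$from, edges$to)), c("A", "B"))
  expect_equal(edges$weight, 0.5)
  expect_equal(isolated_nodes(net)$count, 1L)
  expect_equal(isolated_nodes(net)$labels, "C")

  # tau = 1 keeps only identical participant sets; tau = 0 keeps every
  # strictly positive similarity but never creates zero-weight edges
  recs2 <- dplyr::bind_rows(recs, make_diary(c("p1", "p2"), "D"))
  inc2 <- build_incidence(recs2, "high_swb", "weekday")
  hard <- tidy(project_network(inc2, tau = 1))
  expect_equal(nrow(hard), 1L)
  expect_equal(sort(c(hard$from, hard$to)), c("A", "D"))
  loose <- project_network(inc2, tau = 0)
  expect_true(all(tidy(loose)$weight > 0))
  sims <- cosine_similarity(inc2)
  expect_equal(nrow(tidy(loose)), sum(sims[upper.tri(sims)] > 0))
})

test_that("edges carry the similarity as weight and respect the threshold", {
  recs <- simulate_diaries(leisure_sim_config(n_high = 40, n_low = 40, seed = 21))
  inc <- build_incidence(assign_swb_group(recs), "high_swb", "weekday")
  net <- project_network(inc, tau = 0.4)
  edges <- tidy(net)
  expect_true(all(edges$weight >= 0.4))
  sims <- cosine_similarity(inc)
  for (i in sample.int(nrow(edges), min(20, nrow(edges)))) {
    expect_equal(edges$weight[i], sims[edges$from[i], edges$to[i]])
  }
  # node set equals the post-filter activity universe, isolates included
  keep <- colSums(inc$binary) >= 2
  expect_setequal(igraph::V(net$graph)$name, inc$activities[keep])
})

test_that("activities below the participant floor are removed before projection", {
  recs <- dplyr::bind_rows(
    make_diary(c("p1", "p2"), "A"),
    make_diary(c("p1", "p2"), "B"),
    make_diary("p3", "solo")
  )
  inc <- build_incidence(recs, "high_swb", "weekday")
  net <- project_network(inc, tau = 0.3, min_participants = 2)
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  net1 <- project_network(inc, tau = 0.3, min_participants = 1)
  expect_setequal(igraph::V(net1$graph)$name, c("A", "B", "solo"))
})

test_that("invalid thresholds are rejected", {
  recs <- make_diary(c("p1", "p2"), "A")
  inc <- build_incidence(dplyr::bind_rows(recs, make_diary(c("p1", "p2"), "B")),
                         "high_swb", "weekday")
  expect_error(project_network(inc, tau = 1.5), "tau")
  expect_error(project_network(inc, tau = -0.1), "tau")
})

test_that("pruning removes nodes below both cut-offs and is off by default", {
  star <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star[1, 2:5] <- star[2:5, 1] <- 1
  net <- as_activity_network(star)
  expect_equal(igraph::vcount(prune_inactive(net)$graph), 5L)

  pruned <- prune_inactive(net, min_degree = 2)
  expect_equal(igraph::V(pruned$graph)$name, "a")
  expect_setequal(attr(pruned, "removed"), letters[2:5])

  # 5-node fixture with known degrees: path a-b-c-d plus isolate e
  adj <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj["a", "b"] <- adj["b", "a"] <- 1
  adj["b", "c"] <- adj["c", "b"] <- 1
  adj["c", "d"] <- adj["d", "c"] <- 1
  net2 <- as_activity_network(adj)
  deg <- c(a = 1, b = 2, c = 2, d = 1, e = 0)
  pruned2 <- prune_inactive(net2, min_degree = 2)
  expect_setequal(attr(pruned2, "removed"), names(deg)[deg < 2])
  expect_setequal(igraph::V(pruned2$graph)$name, names(deg)[deg >= 2])
})

test_that("graph exports round-trip node and edge structure", {
  net <- fixture_network_with_isolates(n_nodes = 8, n_isolated = 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 8)
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, tsv)
  el <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_named(el, c("node_a", "node_b", "weight"))
  expect_equal(nrow(el), igraph::ecount(net$graph))
})
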