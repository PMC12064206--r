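triangle_net <- function() {
  adj <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(adj) <- 0
  as_activity_network(adj)
}

path_net <- function(n = 3) {
  adj <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  as_activity_network(adj)
}

test_that("density counts edge presence over possible pairs", {
  expect_equal(net_density(triangle_net()), 1)
  expect_equal(net_density(path_net(3)), 2 / 3)
  one <- as_activity_network(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_error(net_density(one), "fewer than 2")
})

test_that("inclusiveness and the isolate census satisfy their identity", {
  net <- fixture_network_with_isolates(49, 3)
  expect_equal(round(net_inclusiveness(net), 3), 0.939)
  expect_equal(isolated_nodes(net)$count, 3L)

  net <- fixture_network_with_isolates(49, 17)
  expect_equal(round(net_inclusiveness(net), 3), 0.653)

  expect_equal(net_inclusiveness(triangle_net()), 1)
  expect_equal(isolated_nodes(triangle_net())$count, 0L)

  edgeless <- as_activity_network(matrix(0, 5, 5))
  iso <- isolated_nodes(edgeless)
  expect_equal(iso$count, 5L)
  expect_equal(net_inclusiveness(edgeless), 0)

  # pendant pair + 2 singletons
  adj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj["a", "b"] <- adj["b", "a"] <- 1
  iso <- isolated_nodes(as_activity_network(adj))
  expect_equal(iso$count, 2L)
  expect_setequal(iso$labels, c("c", "d"))
})

test_that("mean distance averages hops over mutually reachable pairs only", {
  expect_equal(as.numeric(net_mean_distance(triangle_net())), 1)
  expect_equal(as.numeric(net_mean_distance(path_net(3))), 4 / 3)

  # two disjoint triangles: cross-component pairs are excluded
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  adj[1:3, 1:3] <- 1
  adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  md <- net_mean_distance(as_activity_network(adj))
  expect_equal(as.numeric(md), 1)
  expect_equal(attr(md, "n_reachable_pairs"), 6L)

  expect_error(net_mean_distance(as_activity_network(matrix(0, 3, 3))),
               "edgeless")
})

test_that("weighted distances use inverse similarity as edge length", {
  adj <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj["a", "b"] <- adj["b", "a"] <- 0.5
  adj["b", "c"] <- adj["c", "b"] <- 0.25
  net <- as_activity_network(adj)
  # lengths: a-b = 2, b-c = 4, a-c = 6 -> mean (2 + 4 + 6) / 3
  expect_equal(as.numeric(net_mean_distance(net, weighted = TRUE)), 4)
})

test_that("degree centrality normalises by n - 1 and ranks with competition ties", {
  star <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  star[1, 2:6] <- star[2:6, 1] <- 1
  tab <- degree_centrality(as_activity_network(star))
  expect_equal(tab$centrality[tab$activity == "a"], 1)
  expect_equal(tab$centrality[tab$activity != "a"], rep(1 / 5, 5))
  expect_equal(tab$rank, c(1L, rep(2L, 5)))

  all_one <- degree_centrality(triangle_net())
  expect_true(all(all_one$centrality == 1))
  expect_true(all(all_one$rank == 1L))

  # competition ranking skips after ties: degrees 3,3,2,2,0 on 5 nodes
  adj <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj["a", c("b", "c", "d")] <- adj[c("b", "c", "d"), "a"] <- 1
  adj["b", c("c", "d")] <- adj[c("c", "d"), "b"] <- 1
  tab <- degree_centrality(as_activity_network(adj))
  expect_equal(tab$rank[match(c("a", "b", "c", "d", "e"), tab$activity)],
               c(1L, 1L, 3L, 3L, 5L))
})

test_that("ranking operates on the 2-decimal display values", {
  # two hubs whose exact centralities differ (52/201 vs 53/201) but print
  # identically at 2 d.p. must share a rank
  n <- 202
  lab <- sprintf("v%03d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(lab, lab))
  adj[1, 3:54] <- adj[3:54, 1] <- 1
  adj[2, 3:55] <- adj[3:55, 2] <- 1
  tab <- degree_centrality(as_activity_network(adj))
  hubs <- tab[match(c("v001", "v002"), tab$activity), ]
  expect_false(hubs$centrality[1] == hubs$centrality[2])
  expect_equal(unname(hubs$centrality_2dp), c(0.26, 0.26))
  expect_equal(hubs$rank, c(1L, 1L))
})

test_that("top_activities keeps boundary ties", {
  ten_tied <- degree_centrality(as_activity_network({
    m <- matrix(1, 10, 10)
    diag(m) <- 0
    dimnames(m) <- list(letters[1:10], letters[1:10])
    m
  }))
  kept <- top_activities(ten_tied, k = 10)
  expect_equal(nrow(kept), 10L)
  expect_true(all(kept$rank == 1L))

  # 12 nodes tied at rank 1 with k = 10: all 12 kept
  twelve <- degree_centrality(as_activity_network({
    m <- matrix(1, 12, 12)
    diag(m) <- 0
    dimnames(m) <- list(sprintf("a%02d", 1:12), sprintf("a%02d", 1:12))
    m
  }))
  expect_equal(nrow(top_activities(twelve, k = 10)), 12L)
})

test_that("network_summary assembles consistent indices", {
  s <- network_summary(triangle_net())
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3)
  expect_equal(s$density, 1)
  expect_equal(s$inclusiveness, 1)
  expect_equal(s$mean_distance, 1)
  expect_equal(s$isolated_count, 0L)
  expect_identical(glance(triangle_net()), s)

  # identity inclusiveness == 1 - isolated / n on synthetic networks
  recs <- assign_swb_group(
    simulate_diaries(leisure_sim_config(n_high = 60, n_low = 60, seed = 13))
  )
  for (g in c("high_swb", "low_swb")) {
    net <- project_network(build_incidence(recs, g, "weekday"))
    s <- network_summary(net)
    expect_equal(s$inclusiveness, 1 - s$isolated_count / s$n_nodes)
  }
})

test_that("all indices agree with enumeration oracles on random graphs", {
  withr::local_seed(99)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    adj <- rand_adj(n, runif(1, 0.2, 0.8))
    net <- as_activity_network(adj)
    expect_equal(net_density(net), oracle_density(adj), tolerance = 1e-12)
    expect_equal(net_inclusiveness(net), oracle_inclusiveness(adj),
                 tolerance = 1e-12)
    expect_setequal(isolated_nodes(net)$labels,
                    rownames(adj)[oracle_isolated(adj)])
    cent <- degree_centrality(net)
    ref <- oracle_degree_centrality(adj)
    expect_equal(cent$centrality[match(names(ref), cent$activity)],
                 unname(ref), tolerance = 1e-12)
    if (sum(adj) > 0) {
      ref_md <- oracle_mean_distance(adj)
      md <- net_mean_distance(net)
      expect_equal(as.numeric(md), ref_md$mean, tolerance = 1e-12)
      expect_equal(attr(md, "n_reachable_pairs"), ref_md$n_pairs)
    }
  }
})
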