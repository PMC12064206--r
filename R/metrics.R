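#' Network distribution indices
#'
#' The four classical distribution indices for an undirected activity
#' network: density (realized edges over possible edges, weights ignored),
#' inclusiveness (fraction of nodes with at least one edge), the isolated
#' node census, and mean distance (average unweighted shortest-path length
#' over mutually reachable node pairs; unreachable pairs and isolates are
#' excluded, which keeps the index finite on disconnected networks).
#'
#' @param net An `activity_network`.
#' @name distribution-indices
NULL

#' @rdname distribution-indices
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  n <- igraph::vcount(net$graph)
  if (n < 2L) {
    abort("Density is undefined for networks with fewer than 2 nodes.")
  }
  2 * igraph::ecount(net$graph) / (n * (n - 1))
}

#' @rdname distribution-indices
#' @export
net_inclusiveness <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  n <- igraph::vcount(net$graph)
  if (n < 1L) {
    abort("Inclusiveness is undefined for an empty network.")
  }
  (n - isolated_nodes(net)$count) / n
}

#' @rdname distribution-indices
#' @export
isolated_nodes <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  deg <- igraph::degree(net$graph)
  labels <- names(deg)[deg == 0]
  list(count = length(labels), labels = labels)
}

#' @rdname distribution-indices
#' @param weighted If `TRUE`, use weighted shortest paths with edge length
#'   `1/weight` (stronger ties are shorter); the default counts hops on the
#'   thresholded graph.
#' @export
net_mean_distance <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "activity_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    abort("Mean distance is undefined for an edgeless network.")
  }
  d <- igraph::distances(
    g,
    weights = if (weighted) 1 / igraph::E(g)$weight else NA
  )
  vals <- d[upper.tri(d)]
  reachable <- is.finite(vals) & vals > 0
  out <- mean(vals[reachable])
  attr(out, "n_reachable_pairs") <- sum(reachable)
  out
}

#' Degree centrality with tied ranking
#'
#' Normalized degree centrality (`degree / (n - 1)`) for every node,
#' rounded to two decimals for table display, with competition ranking on
#' the rounded values: tied activities share the smallest applicable rank
#' and the next distinct value skips ranks (1, 2, 2, 2, 5, ...), matching
#' how tied activity rankings are conventionally printed.
#'
#' @param net An `activity_network` with at least 2 nodes.
#' @return A tibble with columns `activity`, `degree`, `centrality`
#'   (exact), `centrality_2dp` (display value) and `rank`, sorted by rank
#'   then activity label.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  n <- igraph::vcount(net$graph)
  if (n < 2L) {
    abort("Degree centrality needs at least 2 nodes.")
  }
  deg <- igraph::degree(net$graph)
  cent <- deg / (n - 1)
  cent2 <- round(cent, 2)
  tibble(
    activity = names(deg),
    degree = as.integer(deg),
    centrality = as.numeric(cent),
    centrality_2dp = cent2,
    rank = as.integer(competition_rank(cent2))
  ) %>%
    arrange(.data$rank, .data$activity)
}

#' Keep the top-ranked activities of a centrality table
#'
#' Keeps every row whose rank is within the top `k`; ties straddling the
#' boundary are all retained, so the result can exceed `k` rows.
#'
#' @param centrality_table A tibble from [degree_centrality()].
#' @param k Rank cut-off (default 10).
#' @return The filtered tibble.
#' @export
top_activities <- function(centrality_table, k = 10) {
  assert_scalar_number(k, "k", lower = 1)
  centrality_table %>% filter(.data$rank <= k)
}

#' Summarise a network's distribution indices
#'
#' One row with the node/edge counts, density, inclusiveness, mean
#' distance (with its reachable-pair count), and the isolated-node census.
#' Available as `glance()` on an `activity_network`.
#'
#' @param net An `activity_network`.
#' @return A one-row tibble with columns `group_label`, `day_type`,
#'   `n_nodes`, `n_edges`, `density`, `inclusiveness`, `mean_distance`,
#'   `n_reachable_pairs`, `isolated_count`, `isolated_labels`
#'   (list-column).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  n <- igraph::vcount(net$graph)
  iso <- isolated_nodes(net)
  if (igraph::ecount(net$graph) > 0L) {
    md <- net_mean_distance(net)
    pairs <- attr(md, "n_reachable_pairs")
  } else {
    md <- NA_real_
    pairs <- 0L
  }
  p <- net$provenance
  tibble(
    group_label = p$group_label %||% NA_character_,
    day_type = p$day_type %||% NA_character_,
    n_nodes = n,
    n_edges = igraph::ecount(net$graph),
    density = if (n >= 2) net_density(net) else NA_real_,
    inclusiveness = net_inclusiveness(net),
    mean_distance = as.numeric(md),
    n_reachable_pairs = as.integer(pairs),
    isolated_count = iso$count,
    isolated_labels = list(iso$labels)
  )
}

#' @export
glance.activity_network <- function(x, ...) {
  network_summary(x)
}
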