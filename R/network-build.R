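#' Cosine similarity between activity (or person) profiles
#'
#' Projects the 2-mode incidence structure onto one mode by computing, for
#' every pair of columns, the cosine of the angle between their
#' person-indexed participation vectors:
#' `sim(a, b) = <x_a, x_b> / (||x_a|| * ||x_b||)`. With binary weighting
#' this is 1 for identical participant sets and 0 for disjoint ones. The
#' diagonal is set to 0.
#'
#' @param incidence An `incidence_matrix` from [build_incidence()].
#' @param weighting `"binary"` (membership vectors) or `"minutes"`
#'   (minute-weighted vectors).
#' @param mode `"activity"` (default; similarity between activity columns)
#'   or `"person"` (similarity between person rows).
#' @return A symmetric numeric matrix with values in `[0, 1]` and zero
#'   diagonal, labelled by activity (or person) name.
#' @examples
#' recs <- tibble::tibble(
#'   person_id = c("a", "a", "b"), age = 15L, sex = "female",
#'   education = "middle", swb_score = 1L, health_score = 1L,
#'   leisure_satisfaction = 3L, day_type = "weekday",
#'   activity_code = c("sleep", "tv", "sleep"), minutes = 30
#' )
#' inc <- build_incidence(recs, "high_swb", "weekday")
#' cosine_similarity(inc)
#' @export
cosine_similarity <- function(incidence,
                              weighting = c("binary", "minutes"),
                              mode = c("activity", "person")) {
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  if (!inherits(incidence, "incidence_matrix")) {
    abort("`incidence` must be an incidence_matrix from build_incidence().")
  }
  if (isTRUE(incidence$empty)) {
    abort("Cannot compute similarities on an empty incidence matrix.")
  }
  m <- if (weighting == "binary") incidence$binary else incidence$weights
  if (mode == "person") {
    m <- t(m)
  }
  if (ncol(m) == 1L) {
    warn("Only one node after filtering: returning a 1x1 zero similarity matrix.")
    return(matrix(0, 1, 1, dimnames = list(colnames(m), colnames(m))))
  }
  cross <- crossprod(m)
  norms <- sqrt(diag(cross))
  sim <- cross / tcrossprod(norms)
  # clamp floating-point noise so identical columns give exactly 1 (the
  # tau = 1 characterisation) and no value escapes [0, 1]
  sim[abs(sim - 1) < 1e-12] <- 1
  sim <- pmin(pmax(sim, 0), 1)
  diag(sim) <- 0
  sim
}

new_activity_network <- function(graph, tau, provenance) {
  structure(
    list(graph = graph, tau = tau, provenance = provenance),
    class = "activity_network"
  )
}

#' Project an incidence matrix to a one-mode activity network
#'
#' Runs the full 2-mode to 1-mode projection: activities with fewer than
#' `min_participants` participants are removed first (single-participant
#' activities carry no co-participation information), cosine similarities
#' are computed on the remaining columns, and an undirected weighted graph
#' is built keeping every pair with similarity `>= tau` (and `> 0`; exact
#' zeros never become edges). Nodes whose every similarity falls below the
#' threshold are retained as isolated nodes — isolation is itself one of
#' the reported indices.
#'
#' @param incidence An `incidence_matrix`.
#' @param tau Similarity threshold in `[0, 1]`; default 0.3.
#' @param weighting,mode Passed to [cosine_similarity()].
#' @param min_participants Minimum participant count for an activity to
#'   enter the projection (default 2).
#' @return An `activity_network`: an igraph graph (edge attribute `weight`
#'   holds the similarity) plus `tau` and a provenance record
#'   `(group_label, day_type, weighting, mode)`.
#' @export
project_network <- function(incidence,
                            tau = 0.3,
                            weighting = c("binary", "minutes"),
                            min_participants = 2,
                            mode = c("activity", "person")) {
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    abort("`tau` must be a single number in [0, 1].")
  }
  assert_scalar_number(min_participants, "min_participants", lower = 1)
  if (mode == "activity") {
    keep <- colSums(incidence$binary) >= min_participants
    incidence$binary <- incidence$binary[, keep, drop = FALSE]
    incidence$weights <- incidence$weights[, keep, drop = FALSE]
    incidence$activities <- incidence$activities[keep]
  }
  sim <- cosine_similarity(incidence, weighting = weighting, mode = mode)
  adj <- sim
  adj[adj < tau | adj <= 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  new_activity_network(
    g, tau,
    list(group_label = incidence$group_label, day_type = incidence$day_type,
         weighting = weighting, mode = mode)
  )
}

#' Construct an activity network from a weighted adjacency matrix
#'
#' Convenience constructor for already-projected (or externally supplied)
#' symmetric adjacency/similarity matrices.
#'
#' @param adjacency Symmetric nonnegative matrix with zero diagonal;
#'   dimnames, if present, become node labels.
#' @param tau Threshold recorded as having produced the network (default 0).
#' @param provenance Optional provenance list.
#' @return An `activity_network`.
#' @export
as_activity_network <- function(adjacency, tau = 0, provenance = list()) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency) ||
      max(abs(adjacency - t(adjacency))) > 1e-12) {
    abort("`adjacency` must be a symmetric square matrix.")
  }
  if (is.null(rownames(adjacency))) {
    lab <- sprintf("node_%02d", seq_len(nrow(adjacency)))
    dimnames(adjacency) <- list(lab, lab)
  }
  diag(adjacency) <- 0
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  new_activity_network(g, tau, provenance)
}

#' Weighted adjacency matrix of an activity network
#'
#' @param net An `activity_network`.
#' @return A symmetric numeric matrix (similarity weights; 0 = no edge).
#' @export
activity_adjacency <- function(net) {
  stopifnot(inherits(net, "activity_network"))
  as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight", sparse = FALSE))
}

#' Prune inactive nodes
#'
#' Removes nodes that fall below *both* cut-offs: degree below `min_degree`
#' and normalized degree centrality below `min_centrality`. With the
#' defaults (`min_degree = 0`) the network is returned unchanged — the
#' distribution indices report isolation rather than hiding it, so pruning
#' is opt-in. The removed labels are attached as the `removed` attribute.
#'
#' @param net An `activity_network`.
#' @param min_degree Degree cut-off (default 0 = no pruning).
#' @param min_centrality Normalized-degree cut-off (default `Inf`, so that
#'   `min_degree` alone decides when only a degree rule is wanted).
#' @return A pruned `activity_network` with a `removed` character attribute.
#' @export
prune_inactive <- function(net, min_degree = 0, min_centrality = Inf) {
  stopifnot(inherits(net, "activity_network"))
  assert_scalar_number(min_degree, "min_degree", lower = 0)
  g <- net$graph
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  cent <- if (n > 1) deg / (n - 1) else deg * 0
  drop <- deg < min_degree & cent < min_centrality
  out <- net
  out$graph <- igraph::delete_vertices(g, which(drop))
  attr(out, "removed") <- names(deg)[drop]
  out
}

#' @export
print.activity_network <- function(x, ...) {
  p <- x$provenance
  who <- if (length(p) > 0) sprintf(" [%s/%s, %s]", p$group_label, p$day_type, p$weighting) else ""
  cat(sprintf(
    "<activity_network>%s %d nodes, %d edges (tau = %s)\n",
    who, igraph::vcount(x$graph), igraph::ecount(x$graph), format(x$tau)
  ))
  invisible(x)
}

#' @describeIn project_network Tidy the edge list of an activity network
#'   into a tibble (`from`, `to`, `weight`).
#' @param x An `activity_network`.
#' @param ... Unused.
#' @export
tidy.activity_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0L) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  el <- igraph::as_data_frame(x$graph, what = "edges")
  as_tibble(el) %>%
    dplyr::rename(weight = "weight") %>%
    arrange(.data$from, .data$to)
}

#' Export a network as GraphML
#'
#' @param net An `activity_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "activity_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Export a network as a tab-separated weighted edge list
#'
#' Columns: `node_a`, `node_b`, `weight`.
#'
#' @param net An `activity_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  el <- tidy(net) %>%
    dplyr::rename(node_a = "from", node_b = "to")
  readr::write_tsv(el, path)
  invisible(path)
}
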