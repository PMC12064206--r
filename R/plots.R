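#' Plot an activity network
#'
#' Force-directed layout (Fruchterman-Reingold, seeded for
#' reproducibility) with edge width proportional to cosine similarity.
#' Isolated nodes are drawn hollow. When a `cohesion_result` is supplied,
#' nodes are coloured by subgroup.
#'
#' @param object An `activity_network`.
#' @param cohesion Optional `cohesion_result` for the same network.
#' @param seed Layout seed.
#' @param label Draw node labels (default `TRUE` for networks up to 60
#'   nodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_network <- function(object, cohesion = NULL, seed = 1L,
                                      label = NULL, ...) {
  g <- object$graph
  lay <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    activity = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2],
    degree = as.integer(igraph::degree(g))
  )
  if (!is.null(cohesion)) {
    nodes <- nodes %>%
      left_join(cohesion$partition, by = "activity") %>%
      mutate(group = factor(.data$group))
  }
  edges <- tidy(object)
  if (nrow(edges) > 0L) {
    edges <- edges %>%
      left_join(nodes %>% select("activity", xa = "x", ya = "y"),
                by = c(from = "activity")) %>%
      left_join(nodes %>% select("activity", xb = "x", yb = "y"),
                by = c(to = "activity"))
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      colour = "grey60", alpha = 0.6
    ) +
      ggplot2::scale_linewidth(range = c(0.1, 1.2), guide = "none")
  }
  aes_pt <- if (is.null(cohesion)) {
    ggplot2::aes(x = .data$x, y = .data$y, shape = .data$degree == 0)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, shape = .data$degree == 0,
                 colour = .data$group)
  }
  p <- p + ggplot2::geom_point(data = nodes, aes_pt, size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none")
  if (isTRUE(label %||% (nrow(nodes) <= 60))) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$activity),
      size = 2.2, vjust = -1, check_overlap = TRUE
    )
  }
  prov <- object$provenance
  title <- if (length(prov) > 0) {
    sprintf("%s / %s (tau = %s)", prov$group_label, prov$day_type,
            format(object$tau))
  } else {
    sprintf("Activity network (tau = %s)", format(object$tau))
  }
  p + ggplot2::labs(title = title) + ggplot2::theme_void()
}

#' Plot a QAP permutation null distribution
#'
#' Histogram of the permuted correlations with the observed correlation
#' marked; the tail beyond the observed value is what the p-value counts.
#'
#' @param object A `qap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qap_result <- function(object, ...) {
  ggplot2::ggplot(tibble(r = object$null_distribution),
                  ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$r_observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "permuted correlation",
      y = "count",
      title = sprintf("QAP null (r = %.3f, p = %.4f, %d permutations)",
                      object$r_observed, object$p_value,
                      object$n_permutations)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a degree-centrality ranking
#'
#' Lollipop chart of the top-ranked activities (ties at the boundary are
#' kept), ordered by centrality.
#'
#' @param centrality_table A tibble from [degree_centrality()].
#' @param k Rank cut-off (default 10).
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality_table, k = 10) {
  top <- top_activities(centrality_table, k = k) %>%
    mutate(activity = stats::reorder(.data$activity, .data$centrality))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$centrality, y = .data$activity)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$centrality,
                                       yend = .data$activity),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2.5, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d", .data$rank)),
                       hjust = -0.8, size = 2.8) +
    ggplot2::labs(x = "normalized degree centrality", y = NULL) +
    ggplot2::theme_minimal()
}
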