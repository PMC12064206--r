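# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (double loops, Floyd-Warshall, full enumeration) so the
# package implementations are checked against a second, independent route.

oracle_cosine <- function(m) {
  k <- ncol(m)
  out <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        out[i, j] <- sum(m[, i] * m[, j]) /
          (sqrt(sum(m[, i]^2)) * sqrt(sum(m[, j]^2)))
      }
    }
  }
  out
}

oracle_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[upper.tri(adj)] > 0) / choose(n, 2)
}

oracle_isolated <- function(adj) {
  which(rowSums(adj > 0) == 0)
}

oracle_inclusiveness <- function(adj) {
  (nrow(adj) - length(oracle_isolated(adj))) / nrow(adj)
}

oracle_degree_centrality <- function(adj) {
  rowSums(adj > 0) / (nrow(adj) - 1)
}

# Unweighted mean shortest-path length over mutually reachable unordered
# pairs, via Floyd-Warshall.
oracle_mean_distance <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  list(mean = mean(v), n_pairs = length(v))
}

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  nij <- s(tab)
  ai <- s(rowSums(tab))
  bj <- s(colSums(tab))
  expected <- ai * bj / choose(length(a), 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}

all_perms <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], p)
    }
  }
  out
}

# Fully enumerated QAP null for small symmetric matrices.
oracle_qap_null <- function(ma, mb) {
  ut <- upper.tri(ma)
  vapply(all_perms(seq_len(nrow(mb))), function(p) {
    cor(ma[ut], mb[p, p][ut])
  }, numeric(1))
}

# Random symmetric binary adjacency matrix (uses the current RNG stream).
rand_adj <- function(n, p, labels = sprintf("n%02d", seq_len(n))) {
  a <- matrix(0, n, n, dimnames = list(labels, labels))
  ut <- which(upper.tri(a))
  a[ut[runif(length(ut)) < p]] <- 1
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# Random symmetric weighted matrix with uniform weights on present edges.
rand_weighted_adj <- function(n, p) {
  a <- rand_adj(n, p)
  ut <- which(upper.tri(a) & a > 0)
  a[ut] <- runif(length(ut), 0.1, 1)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# Compact diary-record builder (vectorised over person/activity).
make_diary <- function(person, activity, day_type = "weekday", minutes = 30,
                       swb = 1L, health = 1L, age = 15L) {
  tibble::tibble(
    person_id = person, age = as.integer(age), sex = "female",
    education = "middle", swb_score = as.integer(swb),
    health_score = as.integer(health), leisure_satisfaction = 3L,
    day_type = day_type, activity_code = activity, minutes = minutes
  )
}

# A 49-node activity network with an exact number of degree-zero nodes,
# built through the package's own ingestion + projection path: the
# connected activities share one participant pair (cosine 1 clique), each
# isolated activity gets a disjoint participant pair (cosine 0 everywhere).
fixture_network_with_isolates <- function(n_nodes = 49, n_isolated = 0,
                                          tau = 0.3) {
  acts <- sprintf("act_%02d", seq_len(n_nodes))
  n_conn <- n_nodes - n_isolated
  recs <- make_diary(
    person = rep(c("p1", "p2"), each = n_conn),
    activity = rep(acts[seq_len(n_conn)], times = 2)
  )
  if (n_isolated > 0) {
    iso_acts <- acts[(n_conn + 1):n_nodes]
    recs <- dplyr::bind_rows(recs, make_diary(
      person = paste0("q", seq_len(2 * n_isolated)),
      activity = rep(iso_acts, each = 2)
    ))
  }
  inc <- build_incidence(recs, "high_swb", "weekday")
  project_network(inc, tau = tau)
}

# Small two-block planted-partition adjacency.
planted_partition_adj <- function(block_size = 10, p_in = 0.8, p_out = 0.05) {
  n <- 2 * block_size
  block <- rep(1:2, each = block_size)
  a <- matrix(0, n, n, dimnames = list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) p_in else p_out
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  list(adj = a, block = block)
}
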