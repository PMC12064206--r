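#' Align two networks on a common node universe
#'
#' Expands both networks' weighted adjacency matrices to the union of the
#' two node sets (sorted), inserting zero rows/columns for nodes absent
#' from one network, so that cellwise comparison is meaningful.
#'
#' @param a,b `activity_network` objects or square named matrices.
#' @return A list with elements `a` and `b`: identically ordered square
#'   matrices.
#' @export
align_networks <- function(a, b) {
  ma <- if (inherits(a, "activity_network")) activity_adjacency(a) else as.matrix(a)
  mb <- if (inherits(b, "activity_network")) activity_adjacency(b) else as.matrix(b)
  if (is.null(rownames(ma)) || is.null(rownames(mb))) {
    abort("Both networks need node labels to be aligned.")
  }
  universe <- sort(union(rownames(ma), rownames(mb)))
  expand <- function(m) {
    out <- matrix(0, length(universe), length(universe),
                  dimnames = list(universe, universe))
    out[rownames(m), colnames(m)] <- m
    out
  }
  list(a = expand(ma), b = expand(mb))
}

upper_vec <- function(m) m[upper.tri(m)]

#' QAP correlation between two networks
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' symmetric network matrices, with significance assessed by the quadratic
#' assignment procedure: the null distribution is generated by repeatedly
#' applying one random node relabelling simultaneously to the rows and
#' columns of the second matrix, which preserves its structure while
#' breaking its alignment with the first. The p-value uses the add-one
#' permutation estimator `(b + 1) / (m + 1)`, so it lies in `(0, 1]`.
#'
#' @param a,b `activity_network` objects or symmetric matrices; networks
#'   are aligned on the union of their node sets first.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @param sidedness `"two_sided"` (default; counts `|r_perm| >= |r_obs|`)
#'   or `"greater"`.
#' @param weighting `"similarity"` correlates the similarity weights
#'   (default); `"binary"` correlates edge presence/absence.
#' @return A `qap_result` with `r_observed`, `p_value`, `n_permutations`,
#'   `null_quantiles` (2.5/50/97.5%), `null_distribution`, `sidedness`,
#'   `seed`.
#' @examples
#' m <- as_activity_network(rbind(c(0, 1, 0.5), c(1, 0, 0), c(0.5, 0, 0)))
#' qap_correlation(m, m, n_permutations = 99, seed = 1)
#' @export
qap_correlation <- function(a, b,
                            n_permutations = 1000,
                            seed = 1L,
                            sidedness = c("two_sided", "greater"),
                            weighting = c("similarity", "binary")) {
  sidedness <- match.arg(sidedness)
  weighting <- match.arg(weighting)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  aligned <- align_networks(a, b)
  ma <- aligned$a
  mb <- aligned$b
  n <- nrow(ma)
  if (n < 3L) {
    abort("QAP needs matrices of dimension >= 3.")
  }
  if (max(abs(ma - t(ma))) > 1e-12 || max(abs(mb - t(mb))) > 1e-12) {
    abort("QAP expects symmetric matrices.")
  }
  if (weighting == "binary") {
    ma <- (ma > 0) * 1
    mb <- (mb > 0) * 1
  }
  va <- upper_vec(ma)
  if (stats::sd(va) == 0) {
    abort("Off-diagonal cells of the first matrix have zero variance; correlation is undefined.")
  }
  if (stats::sd(upper_vec(mb)) == 0) {
    abort("Off-diagonal cells of the second matrix have zero variance; correlation is undefined.")
  }
  r_obs <- cor(va, upper_vec(mb))

  ut <- upper.tri(ma)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      cor(va, mb[p, p][ut])
    }, numeric(1))
  })
  b_count <- switch(sidedness,
    two_sided = sum(abs(r_null) >= abs(r_obs) - 1e-12),
    greater = sum(r_null >= r_obs - 1e-12)
  )
  structure(
    list(
      r_observed = r_obs,
      p_value = (b_count + 1) / (n_permutations + 1),
      n_permutations = as.integer(n_permutations),
      null_quantiles = quantile(r_null, c(0.025, 0.5, 0.975), names = TRUE),
      null_distribution = r_null,
      sidedness = sidedness,
      weighting = weighting,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "qap_result"
  )
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf(
    "<qap_result> r = %.3f, p = %.4f (%s, %d permutations)\n",
    x$r_observed, x$p_value, x$sidedness, x$n_permutations
  ))
  invisible(x)
}

#' @describeIn qap_correlation Tidy a QAP result into a one-row tibble.
#' @param x A `qap_result`.
#' @param ... Unused.
#' @export
tidy.qap_result <- function(x, ...) {
  tibble(
    r_observed = x$r_observed,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    null_q025 = unname(x$null_quantiles[1]),
    null_median = unname(x$null_quantiles[2]),
    null_q975 = unname(x$null_quantiles[3]),
    sidedness = x$sidedness
  )
}

#' @export
glance.qap_result <- function(x, ...) {
  tidy(x)
}

#' Pairwise QAP correlation table
#'
#' Runs [qap_correlation()] for every unordered pair of a named list of
#' networks and returns the lower-triangular correlation table (one row
#' per pair), the conventional layout for reporting network-to-network
#' associations.
#'
#' @param nets Named list of `activity_network` objects (>= 2).
#' @param ... Passed to [qap_correlation()].
#' @return A tibble with `network_a`, `network_b`, `r`, `p_value`.
#' @export
qap_pairwise <- function(nets, ...) {
  if (length(nets) < 2L || is.null(names(nets))) {
    abort("`nets` must be a named list of at least two networks.")
  }
  pairs <- utils::combn(names(nets), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    res <- qap_correlation(nets[[pr[1]]], nets[[pr[2]]], ...)
    tibble(network_a = pr[2], network_b = pr[1],
           r = res$r_observed, p_value = res$p_value)
  })
}
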