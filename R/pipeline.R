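strata <- function() {
  tidyr::expand_grid(
    group_label = c("high_swb", "low_swb"),
    day_type = c("weekday", "weekend")
  )
}

stratum_id <- function(group_label, day_type) {
  paste(group_label, day_type, sep = "_")
}

#' Run the full leisure-network pipeline
#'
#' Orchestrates one end-to-end analysis: obtain diary records (simulate
#' from a configuration, read a CSV, or use a supplied tibble), apply the
#' inclusion filters and well-being grouping, build the four
#' `(group x day type)` incidence matrices in one pass so the activity
#' universes are consistent, project each to a one-mode network, and
#' compute distribution indices, tied centrality rankings with a top-10
#' section, cohesive subgroups, and the pairwise QAP correlation table
#' over the four networks. Optionally writes every table, graph file and a
#' checksummed run manifest to `out_dir`.
#'
#' @param config A [leisure_sim_config()] used when `records` and `path`
#'   are `NULL` (default: the study-scale two-group configuration).
#' @param records Optional diary tibble (takes precedence over `path`).
#' @param path Optional diary CSV path.
#' @param tau,weighting,min_participants Passed to [project_network()].
#' @param prune_min_degree If `> 0`, [prune_inactive()] is applied with
#'   this degree cut-off (pruning is off by default).
#' @param cohesion_method Passed to [detect_cohesive_groups()].
#' @param n_permutations QAP permutation count (default 1000).
#' @param seed Global seed; defaults to `config$seed`.
#' @param top_k Rank cut-off for the reported top activities (default 10).
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Emit stage-level progress messages.
#'
#' @return A `leisure_run` list: `networks` (named list of four
#'   `activity_network`s), `summaries`, `centrality`, `top_activities`,
#'   `cohesion` (list of `cohesion_result`s), `cohesion_summary`, `qap`,
#'   `filter_report`, `stages` (per-stage record/node/edge counts),
#'   `config`, `seed`, and (when written) `manifest`.
#' @export
run_pipeline <- function(config = leisure_sim_config(),
                         records = NULL,
                         path = NULL,
                         tau = 0.3,
                         weighting = c("binary", "minutes"),
                         min_participants = 2,
                         prune_min_degree = 0,
                         cohesion_method = "modularity_greedy",
                         n_permutations = 1000,
                         seed = NULL,
                         top_k = 10,
                         out_dir = NULL,
                         verbose = FALSE) {
  weighting <- match.arg(weighting)
  seed <- seed %||% (if (!is.null(config)) config$seed else 1L)
  say <- function(...) if (verbose) rlang::inform(sprintf(...))
  stages <- list()
  note_stage <- function(stage, ...) {
    stages[[stage]] <<- tibble(stage = stage, detail = sprintf(...))
    say("[%s] %s", stage, stages[[stage]]$detail)
  }

  if (is.null(records)) {
    if (!is.null(path)) {
      records <- read_diary(path)
      note_stage("ingest", "read %d records from %s", nrow(records), path)
    } else {
      records <- simulate_diaries(config, seed = seed)
      note_stage("simulate", "generated %d records (seed %d)", nrow(records), seed)
    }
  } else {
    note_stage("ingest", "using %d supplied records", nrow(records))
  }

  records <- apply_inclusion_filters(records)
  frep <- filter_report(records)
  note_stage("filter", "%d records kept (%s removed)",
             nrow(records), paste(frep$removed, collapse = "/"))
  records <- assign_swb_group(records)

  st <- strata()
  nets <- purrr::pmap(st, function(group_label, day_type) {
    inc <- build_incidence(records, group_label, day_type)
    net <- project_network(inc, tau = tau, weighting = weighting,
                           min_participants = min_participants)
    if (prune_min_degree > 0) {
      net <- prune_inactive(net, min_degree = prune_min_degree)
    }
    net
  })
  names(nets) <- stratum_id(st$group_label, st$day_type)
  note_stage("project", "built %d networks (tau = %s, %s weighting)",
             length(nets), format(tau), weighting)

  summaries <- purrr::map_dfr(nets, network_summary)
  centrality <- purrr::imap_dfr(nets, function(net, id) {
    degree_centrality(net) %>% mutate(network = id, .before = 1)
  })
  top_tbl <- centrality %>%
    group_by(.data$network) %>%
    filter(.data$rank <= top_k) %>%
    ungroup()
  note_stage("metrics", "summaries and centrality tables for %d networks",
             length(nets))

  cohesion <- purrr::map(nets, function(net) {
    if (igraph::ecount(net$graph) == 0L) {
      suppressWarnings(detect_cohesive_groups(net, method = cohesion_method,
                                              seed = seed))
    } else {
      detect_cohesive_groups(net, method = cohesion_method, seed = seed)
    }
  })
  cohesion_summary <- purrr::imap_dfr(cohesion, function(res, id) {
    glance(res) %>% mutate(network = id, .before = 1)
  })
  note_stage("cohesion", "subgroup counts: %s",
             paste(cohesion_summary$n_groups, collapse = "/"))

  qap <- qap_pairwise(nets, n_permutations = n_permutations, seed = seed)
  note_stage("qap", "%d pairwise correlations (%d permutations each)",
             nrow(qap), n_permutations)

  run <- structure(
    list(
      networks = nets, summaries = summaries, centrality = centrality,
      top_activities = top_tbl, cohesion = cohesion,
      cohesion_summary = cohesion_summary, qap = qap,
      filter_report = frep, stages = bind_rows(stages),
      config = config, tau = tau, weighting = weighting,
      seed = as.integer(seed)
    ),
    class = "leisure_run"
  )

  if (!is.null(out_dir)) {
    run$manifest <- write_run_outputs(run, out_dir)
    note_stage("write", "outputs written to %s", out_dir)
  }
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(rel, writer) {
    p <- file.path(out_dir, rel)
    writer(p)
    files[[rel]] <<- unname(tools::md5sum(p))
  }
  put("network_summaries.csv", function(p) {
    readr::write_csv(run$summaries %>%
                       mutate(isolated_labels = purrr::map_chr(
                         .data$isolated_labels, paste, collapse = ";")), p)
  })
  put("degree_centrality.csv", function(p) readr::write_csv(run$centrality, p))
  put("top_activities.csv", function(p) readr::write_csv(run$top_activities, p))
  put("qap_correlations.csv", function(p) readr::write_csv(run$qap, p))
  for (id in names(run$networks)) {
    net <- run$networks[[id]]
    put(sprintf("network_%s.graphml", id), function(p) write_graphml(net, p))
    put(sprintf("edges_%s.tsv", id), function(p) write_edgelist(net, p))
    res <- run$cohesion[[id]]
    put(sprintf("partition_%s.csv", id), function(p) write_partition_csv(res, p))
  }
  put("run_config.json", function(p) {
    cfg <- list(
      tau = run$tau, weighting = run$weighting, seed = run$seed,
      n_activities = run$config$n_activities %||% NA,
      n_high = run$config$profiles$high_swb$n_respondents %||% NA,
      n_low = run$config$profiles$low_swb$n_respondents %||% NA
    )
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, pretty = TRUE)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("leisurenet")),
    r_version = R.version.string,
    seed = run$seed,
    written_at = format(Sys.time(), tz = "UTC"),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.leisure_run <- function(x, ...) {
  cat(sprintf("<leisure_run> %d networks (tau = %s, %s weighting, seed %d)\n",
              length(x$networks), format(x$tau), x$weighting, x$seed))
  print(x$summaries %>% select(-"isolated_labels"))
  invisible(x)
}

#' Sweep the projection threshold over a grid
#'
#' Re-projects one incidence matrix at each threshold in `taus` and
#' tabulates edge count, density, inclusiveness and isolated-node count —
#' a direct view of how sensitive the network is to the (study-unreported)
#' threshold choice. Density and inclusiveness are nonincreasing, and
#' isolation nondecreasing, in `tau`.
#'
#' @param incidence An `incidence_matrix`.
#' @param taus Numeric vector of thresholds in `[0, 1]`.
#' @param ... Passed to [project_network()].
#' @return A tibble with one row per threshold.
#' @export
tau_sweep <- function(incidence, taus = seq(0.1, 0.9, by = 0.1), ...) {
  purrr::map_dfr(taus, function(tau) {
    net <- project_network(incidence, tau = tau, ...)
    network_summary(net) %>%
      select("n_nodes", "n_edges", "density", "inclusiveness",
             "isolated_count") %>%
      mutate(tau = tau, .before = 1)
  })
}
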