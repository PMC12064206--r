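# leisurenet

Social-network analysis of leisure-activity co-participation from
time-use diaries, for researchers studying how activity repertoires
differ between groups of respondents — here, adolescents stratified by
subjective well-being (SWB).

Time-use diaries record which activities each respondent performed over a
day and for how long. `leisurenet` treats these records as a 2-mode
(bipartite) network of persons and activities, projects it onto the
activity mode, and compares the resulting 1-mode networks between groups.

## Method

For a stratum (group × day type), let **B** be the persons × activities
incidence matrix (binary membership, or total minutes). Activities with
fewer than 2 participants are dropped, and every pair of activity columns
is scored by cosine similarity

```
sim(a, b) = <x_a, x_b> / (||x_a|| · ||x_b||)
```

over person-indexed participation vectors. An undirected weighted network
keeps each pair with `sim ≥ τ` (default τ = 0.3), carrying the similarity
as edge weight; activities whose every similarity falls below τ remain as
isolated nodes. On each network the package computes:

- **density** = 2E / (N(N−1)) — realized over possible edges;
- **inclusiveness** = (N − isolates) / N — fraction of non-isolated nodes;
- **mean distance** — average shortest-path length (hops) over mutually
  reachable pairs;
- **degree centrality** = degree / (N−1), ranked with competition
  ("1224") ties on 2-decimal display values;
- **cohesive subgroups** via greedy modularity maximisation on the
  similarity weights;
- **QAP correlation** between networks: Pearson correlation of
  off-diagonal upper triangles, with significance from repeated
  simultaneous row/column permutations of one matrix and the add-one
  estimator p = (b + 1) / (m + 1).

Because national time-use microdata are access-restricted, the package
includes a first-class synthetic diary generator (two groups of 241
respondents over a 49-activity universe by default) whose group profiles
reproduce the qualitative contrast the analysis is designed to detect:
a dense, diverse high-SWB network versus a sparse, fragmented low-SWB
network.

## Worked example

```r
library(leisurenet)

cfg <- leisure_sim_config(seed = 42)   # 241 + 241 respondents, 49 activities
run <- run_pipeline(cfg, n_permutations = 1000)

dplyr::select(run$summaries, group_label:inclusiveness, isolated_count)
#>   group_label day_type n_nodes n_edges density inclusiveness isolated_count
#> 1 high_swb    weekday       49     872  0.741          0.939              3
#> 2 high_swb    weekend       49     926  0.787          0.959              2
#> 3 low_swb     weekday       49      63  0.0536         0.449             27
#> 4 low_swb     weekend       49      66  0.0561         0.449             27
```

The high-SWB group's networks are far denser (0.74–0.79 vs ≈ 0.05) and
more inclusive (0.94–0.96 vs 0.45): high-SWB respondents co-participate
across most of the activity universe while low-SWB participation leaves
over half of the activities isolated. Cohesion shows the same contrast —
the low-SWB networks fragment into more subgroups:

```r
run$cohesion_summary[, c("network", "n_groups", "n_isolates", "modularity")]
#> 1 high_swb_weekday        2          3   0.00328
#> 2 high_swb_weekend        2          2   0.000400
#> 3 low_swb_weekday         4         27   0.0569
#> 4 low_swb_weekend         4         27   0.0573
```

and the QAP table quantifies how similar the four networks are to each
other (the low-SWB weekday and weekend networks correlate at 0.857 —
repetition of the same narrow repertoire — while high-vs-low correlations
sit near 0.29):

```r
run$qap
#>   network_a        network_b            r  p_value
#> 1 high_swb_weekend high_swb_weekday 0.919 0.000999
#> 2 low_swb_weekday  high_swb_weekday 0.294 0.000999
#> ...
#> 6 low_swb_weekend  low_swb_weekday  0.857 0.000999
```

Per-network centrality rankings (`run$top_activities`), tidied edge lists
(`tidy(net)`), summaries (`glance(net)`), and plots
(`autoplot(net)`, `autoplot(qap_result)`, `plot_centrality(tab)`) are
available on every result object, and `run_pipeline(..., out_dir = "out")`
writes all tables, GraphML/edge-list graph files and a checksummed
manifest.

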