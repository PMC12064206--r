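---
title: "Methods: leisure-activity co-participation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leisure-activity co-participation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leisurenet)
```

## The analysis

`leisurenet` asks a structural question about time-use diaries: not *how
often* each leisure activity is performed, but *which activities travel
together* across respondents, and how that co-participation structure
differs between groups. The motivating application contrasts adolescents
with high versus low subjective well-being (SWB): on two survey scales
where higher scores indicate a worse state, the high-SWB group is defined
by a well-being score of 1–4 **and** a health score of 1–2, the low-SWB
group by well-being 5–7 **and** health 3–5. The two rules are applied
jointly, so records satisfying a mixture of the two (say, good well-being
but poor health) are excluded and the groups stay disjoint. Respondents
outside ages 10–19, duplicated `(person, day type, activity)` rows, and
rows missing mandatory fields are removed before analysis, with removals
tallied per rule rather than silently dropped.

## From diaries to networks

Each `(group, day type)` stratum yields a persons × activities incidence
matrix: binary membership plus summed minutes. The 2-mode structure is
projected onto the **activity** mode with cosine similarity between
activity columns. Two design points deserve comment:

* **Projection mode.** Descriptions of this kind of pipeline sometimes
  speak of similarity "between individuals", but the quantities reported
  downstream (density, inclusiveness, centrality ranks, subgroups) all
  concern activity nodes. The package therefore projects onto activities
  by default; `mode = "person"` provides the person-mode projection
  behind the same interface.
* **Weighting.** Binary incidence drives the default analysis path —
  co-participation is a membership notion. The `minutes` weighting feeds
  minute-weighted vectors through the identical code path for
  sensitivity analysis.

Edges are kept when `sim ≥ τ`. The threshold is genuinely a free
parameter of such analyses and is rarely reported; the package defaults
to **τ = 0.3** — for independent participation with marginal rates
`p, q`, the expected binary cosine is roughly `sqrt(pq)`, so τ = 0.3
retains pairs whose joint participation is compatible with both rates
exceeding ~0.3, while cutting the incidental overlap between rare
activities — and ships `tau_sweep()` so every analysis can report its
sensitivity to the choice. Activities with fewer than 2 participants are
removed before projection (a single participant carries no
co-participation signal); beyond that, **pruning of weakly connected
nodes is off by default** (`prune_inactive()` defaults to a no-op),
because isolated-node counts are themselves a reported index — removing
low-degree nodes first would make inclusiveness tautological.

## Indices and their conventions

* **Density** counts edge presence over `N(N−1)/2` pairs; weights are
  ignored.
* **Inclusiveness** is `(N − isolates)/N`, an exact identity with the
  isolated-node census — the package asserts this identity on every
  summary.
* **Mean distance** averages unweighted shortest-path lengths over
  *mutually reachable* unordered pairs; unreachable pairs and isolates
  are excluded, which is the only convention under which disconnected
  networks (isolates present) can report the finite mean distances these
  analyses conventionally print. The reachable-pair count is reported
  alongside. A weighted variant (edge length `1/weight`) exists but is
  non-default, since no standard weighted-distance convention exists for
  similarity weights.
* **Degree centrality** is `degree/(N−1)`, rounded to two decimals for
  display, with competition ranking *on the rounded values*: published
  tables of this kind print 2-d.p. indices with tied ranks, so ranking
  the display values is what makes ranks reproducible from the printed
  table. Top-k reporting keeps all rows tied at the boundary.
* **Cohesive subgroups** default to greedy modularity maximisation on
  the similarity weights (deterministic), with Louvain-style multilevel
  and plain connected-components methods behind the same interface. The
  vertex order is fixed (sorted labels) before clustering and group ids
  are relabelled by descending size then smallest member, so results are
  reproducible across sessions. Isolates become flagged singleton
  groups and are not counted in `n_groups`. Thematic *naming* of
  subgroups is a human judgement and stays out of scope; memberships are
  exported for labelling.
* **QAP correlation** correlates the off-diagonal upper triangles of two
  aligned matrices (symmetric matrices make the full off-diagonal
  redundant). The null permutes the rows and columns of *one* matrix by
  a common random relabelling per iteration — the standard one-matrix
  convention. The p-value uses the add-one estimator `(b+1)/(m+1)`,
  which is never exactly zero and is the standard bias-safe permutation
  estimator. Default 1,000 permutations, two-sided.

## The synthetic generator

National time-use microdata are access-restricted, so the generator is a
first-class module, not a test fixture. It emulates the minimal
structure the analysis consumes:

* two groups (241 respondents each by default) over a 49-activity
  universe; 32 labels follow activity names standard in leisure-survey
  taxonomies and 17 fill out the universe;
* per-activity participation probabilities organised in tiers. The
  high-SWB profile spreads mass widely (10 core activities at 0.80, 24
  at 0.45, 9 at 0.30, 6 rare at 0.08; entropy 3.77 nats) and gets a
  weekend boost (×1.15); the low-SWB profile concentrates it (5 core at
  0.75, 6 at 0.32, 12 at 0.10, 26 rare at 0.03; entropy 3.18 nats) with
  a slight weekend damping (×0.95). Under the `sqrt(pq)` cosine
  approximation these tiers were chosen once so that, at τ = 0.3, the
  high group's mid tier stays connected while the low group's light and
  rare tiers fall below threshold — a dense, inclusive high-SWB network
  versus a sparse one with many isolates, the direction the analysis is
  designed to detect;
* one weekday and one weekend diary per respondent (days per respondent
  is a parameter, not an assertion about any particular survey design);
  activities drawn independently per respondent-day; lognormal
  durations (mean 60, sd 45 minutes) rounded to 5-minute slots; scores
  uniform within each group's range — range criteria are all the
  grouping consumes, so no latent-trait model is imposed.

What it deliberately does **not** model: clock placement within the day
(the analysis only uses co-participation, so a 24-hour grid would be
dead weight), correlations between activities within a respondent beyond
the marginal tiers, survey weights, and household structure. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
a known planted contrast — not that any particular empirical dataset
exhibits it.

## Numerical choices and degenerate inputs

* Cosine values are clamped to `[0, 1]` and values within `1e-12` of 1
  are snapped to 1, so "identical participant sets" is an exact
  characterisation at `τ = 1`.
* Ties at exactly τ are kept (`≥` comparison); exact-zero similarities
  never become edges, even at τ = 0.
* Empty strata, edgeless networks, single-activity matrices and
  zero-variance QAP inputs return flagged empty values, warnings, or
  errors naming the offending input — never silent results.
* All seeded functions restore the caller's RNG state.

## Problem sizes used by the test-suite

The suite checks metrics against exhaustive enumeration oracles on 200
random graphs of up to 8 nodes; the QAP null against the fully
enumerated 24-permutation distribution at n = 4 and its type-I error
over 500 independent-graph replicates of 999 permutations; and direction
recovery over 20 generator seeds at the full 241 + 241 scale. These
sizes make every distributional claim checkable in well under a minute
apiece while keeping the oracles genuinely exhaustive.

## Known limitations

The cohesive-subgroup *counts* depend on the community-detection
algorithm and the unreported threshold of any given published analysis;
only the fragmentation direction (low-SWB at least as fragmented as
high-SWB) is treated as a reproducible claim. Mean-distance comparisons
across networks with different isolate counts average over different
pair sets and should be read accordingly. The generator's independence
assumption tends to produce one large connected block per group rather
than rich multi-community structure, so absolute subgroup counts on
synthetic data are smaller than in real diaries.
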