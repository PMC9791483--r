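# playnet

Coherence statistics and transition networks for dyadic toy-play event
series.

## The problem

When a toddler and a parent play freely in a room full of toys, the
resulting stream of toy selections — who handled what, and what the parent
talked about, in each 5-second segment — is not a string of unrelated
events. Like the sentences of a coherent narrative, it shows a
characteristic suite of statistics: a Zipf-like skew in which a few
"Topic" toys dominate, bursty same-toy runs interleaved with returns after
long delays, close-in-time coordination between the partners, and a sparse
transition network that ties all the selected toys together through the
high-frequency ones. `playnet` measures this suite on coded event tables
and tests each component against a frequency-preserving permutation null —
the hypothesis that everything follows from the skewed selection
frequencies alone.

The package is aimed at developmental and behavioural researchers working
with coded interaction time series: one row per selection event
(`dyad, segment, agent, act, toy`), 121 five-second segments per session,
up to 32 toys.

## What it computes

For each dyad's event series, with `S_j` the selection count of toy `j`
and the *Topics* its five most-selected toys:

* **Rank–frequency distributions** per behaviour stream (toddler handling,
  parent handling, parent talk), with paired Wilcoxon tests on the
  rank-aligned distributions and Spearman correlations over the full
  32-toy universe (d.f. = 31).
* **Cluster statistics**: maximal runs of consecutive segments occupied by
  the same toy — number of clusters and run lengths, for Topic vs Comment
  toys, against the mean of 10,000 label permutations that hold the
  (agent, act, segment) scaffold fixed and preserve every `S_j` exactly.
* **Quartile recurrence profiles**: normalised Topic/Comment selection
  frequencies in each 2.5-minute quarter of the session.
* **Cross-recurrence lags**: for every (toddler event, parent event) pair
  on the same toy, the signed lag `(t_parent − t_toddler) × 5 s`; positive
  lags mean the toddler led.
* **Transition networks**: nodes are selected toys; same-segment and
  adjacent-segment event pairs contribute S (self-loop) and D (edge)
  weights; per node: S/D strength, degree, betweenness, clustering
  coefficient — on the observed network and on the "Random" network built
  from mean permuted transition counts.
* **Within-dyad 2×2 ANOVAs** (Observed–Random × Topic–Comment, both
  factors within) for every cluster and network measure.

A seeded synthetic generator (`simulate_dyad()`) produces dyads with the
same signatures from a reinforced-urn mechanism with focal-toy persistence
and partner coupling, and `simulate_null()` produces memoryless control
dyads; the whole pipeline is testable without any coded video data.

## Worked example

The package's running example is a six-event table spanning three
segments:

```r
library(playnet)
events <- data.frame(
  toy     = c("bucket","hippo","hippo","hippo","giraffe","hippo"),
  agent   = c("toddler","parent","parent","toddler","parent","toddler"),
  act     = c("handle","handle","talk","handle","handle","handle"),
  segment = c(10, 10, 10, 11, 11, 12))
s <- dyad_series(events, dyad_id = "example")

pairs <- enumerate_pairs(s)
table(pairs$kind)
#> D S
#> 8 4
```

Twelve close-in-time pairs: four S pairs (all hippo–hippo — repeated
selection of the same toy by different acts or in adjacent segments) and
eight D pairs. They accumulate into a triangle network:

```r
net <- node_measures(build_network(pairs), clustering = "binary")
net$s_weight
#>  bucket giraffe   hippo
#>       0       0       4
net$d_weight
#>         bucket giraffe hippo
#> bucket       0       1     3
#> giraffe      1       0     4
#> hippo        3       4     0
net$measures[c("toy","degree","betweenness","clustering_coefficient")]
#>       toy degree betweenness clustering_coefficient
#> 1  bucket      2           0                      1
#> 2 giraffe      2           0                      1
#> 3   hippo      2           0                      1
```

Hippo carries the only self-loops (s_weight 4) and the strongest edges;
in a 3-node triangle every node has degree 2, no betweenness, and full
transitivity. Hippo is selected in three consecutive segments — one
cluster with a run length of 3 (15 s of sustained joint attention):

```r
find_clusters(occupancy(s, "hippo"))
#> [1] 3
```

The toddler's hippo handling (segments 11, 12) follows the parent's two
hippo acts (segment 10), so all four cross-recurrence lags are negative —
parent-led, 5–10 s ahead:

```r
cross_recurrence(s)$lags$lag_s
#> [1]  -5 -10  -5 -10
```

At cohort scale, `run_pipeline()` (or the numbered scripts under
`analysis/`) chains everything — simulation or file input, frequency
statistics, permutation baselines, networks, ANOVAs — into a
`cohort_report` with per-dyad tables and group summaries.

## The analysis workflow

The `analysis/` directory is a numbered, re-runnable version of the full
study analysis on a simulated cohort:

| script | what it does |
| --- | --- |
| `01_simulate_cohort.R` | generates 32 dyads, writes `results/cohort_events.csv` |
| `02_frequency_distributions.R` | rank–frequency tables, stream comparisons, Topic/Comment partitions |
| `03_temporal_structure.R` | clusters and run lengths vs the permutation null, quartile profiles, cross-recurrence |
| `04_networks.R` | observed and permutation-mean networks, node measures, 2×2 ANOVAs |
| `05_cohort_report.R` | one-shot consolidated report via `run_pipeline()` |

Each script reads its inputs from `results/`, prints what it found, and
writes tidy CSVs there.

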