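---
title: "Coherence statistics of dyadic toy play: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence statistics of dyadic toy play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playnet)
```

## The data model

`playnet` analyses time series of *toy-selection events* recorded during
free-flowing parent–toddler play. A session is binned into 5-second
segments (121 by default, the coded grid of a standard 10-minute session);
each event is one referential act on a toy — toddler handling, parent
handling, or parent talk about the toy — stamped with its segment. Toddler
talk is not a coded act: young toddlers talk rarely and unreliably, and
their contributions surface through handling. An event is identified by
the tuple (toy, agent, act, segment); an act bridging two segments is coded
as two events, and exact duplicates are collapsed on input.

The toy universe defaults to the observed toys padded to 32 (the size of
the toy room), so never-selected toys exist with zero counts. This matters
for the full-universe Spearman correlations, which are computed over all
32 toys (31 degrees of freedom), zeros included, with average ranks for
ties.

The 121st segment is treated as a fixed constant of the coding grid rather
than derived from the nominal 10-minute duration (which would give 120
bins); sessions run marginally past the nominal end and the grid is what
the coded data use. `n_segments` is configurable throughout.

## The statistics

**Rank–frequency and stream comparisons.** Per behaviour stream, toys are
ranked by selection count; proportions are normalised by the stream total.
Two within-dyad tests compare streams: a paired Wilcoxon signed-rank test
on the *rank-aligned* count vectors (count at rank *i* in one stream
against count at rank *i* in the other, padded with zeros to the universe
size) — the only pairing that compares distribution *shape* while ignoring
toy identity — and a Spearman correlation on per-toy counts, which asks
whether the streams favour the *same* toys. When the rank-aligned vectors
are identical every paired difference is zero; `wilcox.test()` cannot
process an all-zero difference vector, so the statistic is reported as
`V = 0, p = 1` by convention. Otherwise the `stats::wilcox.test()`
defaults apply (zero differences dropped). The original analysis does not
state its zero/tie policy, so printed V statistics may not be exactly
recoverable under any single convention; the choice here is documented
rather than asserted.

**Topic/Comment partition.** Each dyad's five most frequently selected
toys (aggregate count over all three behaviours) are its *Topics* — the
high-frequency, "given" content of the play narrative; the remaining
selected toys are *Comments*, the "new" content. Ties at the rank-5
boundary are broken by earlier first selection, then lexicographically by
toy id, making the partition deterministic and invariant to input row
order. If fewer than five toys were selected, all are Topics.

**Clusters and run lengths.** For each toy, the segment grid is collapsed
to a boolean occupancy vector (at least one act by anyone in the segment).
A *cluster* is a maximal run of at least `min_run` consecutive occupied
segments, default 2: this is the strict reading of "at least two
selections in adjacent segments". Cluster counts are reported per toy
within category (Topics divide by 5, Comments by the number of comment
toys the dyad referenced) or as per-dyad totals (`aggregate = "total"`).

The default `min_run = 2` has a consequence worth knowing: for
low-frequency toys a frequency-preserving permutation scatters selections
into *singleton* occupied segments, which the ≥2 rule does not count, so
under that rule the random baseline can show *fewer* comment clusters than
the observed data. Published group-level cluster tables for this paradigm
report random-baseline mean run lengths *below 2*, which is only possible
if singleton runs are included in the averaging. The package therefore
exposes `min_run = 1` (count every maximal run, singletons included), and
the analysis scripts and acceptance checks use it for the
observed-vs-random contrast: under it, permutation provably cannot
decrease the run count of any toy, so the direction of the contrast
reflects temporal coherence rather than a thresholding artifact.

**The permutation null.** The random baseline shuffles toy labels over the
event list while holding the (agent, act, segment) scaffold fixed: per-toy
aggregate frequencies, per-segment event counts, and the total event count
are all preserved exactly, while every temporal dependence between
selections of the same toy is destroyed. This instantiates the null
hypothesis that a statistic's value follows from the skewed frequency
distribution alone. Ensembles default to 10,000 permutations with a
caller-supplied seed; every statistic is recomputed per permutation and
the mean transition matrix is accumulated for the Random networks.

A shuffle can place two identical tuples in the same (agent, act, segment)
slot. Such shuffles are rejected and redrawn. For heavily skewed label
multisets collision-free shuffles can be vanishingly rare (acceptance
probability below 1e-4), so the engine decides once per ensemble, from 100
trial draws, whether rejection is feasible; if not, labels are shuffled
unconditionally and duplicate tuples are carried through the slot-indexed
statistics (occupancy and pair counts are unaffected by tuple identity).
This keeps the ensemble well-defined and exactly frequency-preserving for
every input. On series where rejection is feasible the sampler is exactly
uniform over valid assignments, which the tests verify against exhaustive
enumeration on a six-event instance.

**Quartile profiles.** The session splits into four quartiles of 30, 30,
30 and 31 segments (2.5 minutes each, the final quartile absorbing the odd
segment). Each quartile is scored by the within-quartile proportion of
selections going to each category, divided by 5 for Topics and by the
number of referenced Comment toys for Comments. A flat Topic profile means
the main-theme toys recur throughout the session rather than being
confined to one phase of play.

**Cross-recurrence lags.** For every pair of a toddler handling event and
a parent event (handling or talk) on the same toy, the lag is
(parent segment − toddler segment) × 5 s; positive lags mean the toddler
selected first. *All* pairs over the session are counted, not only
nearest neighbours, so a toy revisited late in play contributes long lags
by design. The proportion of positive lags is computed over nonzero lags:
same-segment pairs cannot tell who led at the 5-s resolution.
`proportion_positive` above one half indicates toddler-led coordination.

**Transition networks.** Every unordered pair of distinct events in the
same or adjacent segments is a *transition*: S pairs (same toy) accumulate
as self-loop weights, D pairs (different toys) as symmetric edge weights.
Per node the package reports S strength, D strength, degree (distinct
neighbours on the binarized D graph; self-loops never count), betweenness
(unweighted shortest paths on the binarized graph, endpoints excluded,
multiple shortest paths contributing fractionally, raw counts rather than
normalised), and a clustering coefficient. *Random* networks take as edge
weights the mean pair counts over the permutation ensemble — fractional
weights instantiating the frequency-only null — with the same measures and
a configurable presence threshold (default: any positive weight).

**Why the clustering coefficient is weighted by default.** A
permutation-mean network is dense: over thousands of shuffles nearly every
toy pair co-occurs at least once, so with a zero threshold its binarized
graph is near-complete. On a complete graph the *binary* local clustering
coefficient is 1 for every node, which would force observed ≤ random by
construction — the opposite of what dense-but-weak random edges should
mean. The default is therefore an Onnela-style weighted coefficient (mean
geometric triangle intensity with weights normalised by the network
maximum, adjacency from the binarized graph), which discounts the random
network's many weak triangles; `clustering = "binary"` gives the classic
coefficient (and is what the brute-force oracle tests check). Degree and
betweenness stay binarized: their observed-vs-random contrasts are
informative precisely because the random graph is dense. igraph provides
the graph machinery; the Onnela coefficient is computed directly since
igraph implements the Barrat variant, which degenerates to the binary
coefficient on near-complete graphs.

**Within-subject contrasts.** Every Observed×Random by Topic×Comment
contrast is a two-factor repeated-measures ANOVA with both factors within
dyad, fitted through `stats::aov()` error strata and verified in the tests
against hand-computed sums of squares. No sphericity correction is
applied: all 2×2 effects have one degree of freedom, where sphericity is
moot; the 2×4 quartile analysis is reported uncorrected and documented as
such. The conventional α of 0.01 is a reporting annotation, not a filter —
p-values are emitted at full precision. Dyads lacking a complete 2×2 cell
set (for example a dyad with no Comment clusters at all) are dropped from
that contrast, with the retained count reported alongside the F ratios.

## The synthetic dyad generator

No generative model accompanies the original analysis; the generator here
is the package's own construct, built to produce the four signatures the
analysis is designed to detect — skewed frequencies, bursty same-toy runs,
returns after long delays, and close-in-time partner coupling — from one
minimal mechanism:

* per segment, an event count is drawn Poisson(`events_per_segment_rate`),
  and each event is toddler handling, parent handling or parent talk with
  probabilities 0.364/0.300/0.336 (the per-behaviour event shares implied
  by typical per-behaviour segment occupancies of roughly 0.86/0.70/0.80);
* a *focal toy* (the toddler's current object of interest) persists across
  segments with probability `persistence_rho`, else is redrawn from a
  reinforced urn in which each selected toy weighs
  count^`reinforcement_gamma` and the pool of never-selected toys weighs
  `novelty_alpha` in total;
* toddler handling targets the focal toy; parent acts copy the focal toy
  with probability `coupling_kappa`, else draw from the urn; every event
  reinforces its toy.

Defaults (`n_toys = 32`, `n_segments = 121`, rate 2.4, α = 10, γ = 0.65,
ρ = 0.6, κ = 0.5) were fixed once against the engagement profile of
free-flowing toddler play: about 91% of segments contain a selection
(Poisson(2.4) leaves 9% empty), toddlers handle ~15 unique toys, and the
five most-selected toys take just under 60% of selections. The sublinear
γ matters: a linear urn (γ = 1) concentrates play onto 3–4 toys and pushes
the top-5 share above 0.9, far beyond anything observed. All randomness
flows through one seeded stream per call; generation is a pure function of
(parameters, seed), and the caller's RNG state is restored on exit.

`simulate_null()` is the matching memoryless generator: events i.i.d.
across segments from a fixed toy distribution, no persistence,
reinforcement or coupling. Its only temporal structure is sampling noise,
so every temporal statistic must sit at its own permutation-baseline mean
— the calibration property the tests check.

What the generator does *not* emulate: real dyads' three behaviour streams
have near-identical distribution shapes, while the generator's toddler
stream (always focal) is more concentrated than its parent streams, so
within-dyad Wilcoxon comparisons reject more often than in coded data; toy
semantics, spatial layout and parental scaffolding strategies are absent;
and run-length magnitudes are shorter than in real play. Passing tests on
synthetic cohorts therefore certify the *machinery* (measures, null,
contrasts, directions of effects), not the empirical magnitudes of real
play, which require the archived study data.

## Problem sizes and numerical choices

The analysis scripts and the acceptance script run 32 dyads × 121 segments
with 1000 permutations per dyad, sizes at which permutation means are
stable to well under their between-dyad spread; the test suite uses 10,000
permutations where a distributional property itself is under test
(calibration bands, exhaustive-enumeration comparisons) and 200–400
elsewhere. Degenerate inputs resolve to flagged values rather than errors
where the quantity is well-defined-empty (empty rank table, empty lag
profile) and to errors where it is not (empty series in the permutation
engine, empty network in the measures). Betweenness ties are handled
fractionally; rank ties deterministically (first selection, then
lexicographic); quartile proportions in empty quartiles are 0.

## Known limitations

* Observed–Random comparisons depend on the cluster-counting convention;
  both conventions are exposed and the default is the strict ≥2 reading
  (see above). Group-level tables should state `min_run`.
* The Wilcoxon and Spearman conventions above are choices among
  unspecified alternatives; exact reproduction of printed test statistics
  from archived data may require matching the original software's
  defaults.
* Betweenness is reported unnormalised; its scale grows with network size
  and is comparable across networks of similar order only.
* The permutation engine's unconstrained fallback abandons the
  duplicate-tuple rejection rule for extremely skewed inputs; ensembles
  mixing both regimes are never produced, and the mode is decided
  deterministically under the ensemble seed.
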