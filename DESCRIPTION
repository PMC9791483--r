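Package: playnet
Title: Coherence Statistics and Transition Networks for Dyadic Toy-Play Event Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time series of toy-selection events recorded
    during parent-toddler free play. Selection events (toddler handling,
    parent handling, parent referential talk) binned into 5-second segments
    are summarised as rank-frequency distributions with a Topic/Comment
    partition, cluster and run-length statistics against a
    frequency-preserving permutation null, cross-recurrence lag profiles
    between the two partners, and weighted transition-pair networks with
    node-level measures (strength, degree, betweenness, clustering) compared
    against permutation-mean random networks. Includes a seeded synthetic
    dyad generator with reinforcement, persistence and partner-coupling
    dynamics, a memoryless null generator, a two-factor within-subject ANOVA
    helper, and a cohort pipeline producing group-level reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
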