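test_that("occupancy collapses agents and acts per segment", {
  s <- table1_series()
  occ <- occupancy(s, "hippo")
  expect_true(all(occ[10:12]))
  expect_equal(sum(occ), 3L)
  expect_false(any(occupancy(s, "unselected_01")))
  expect_error(occupancy(s, "dragon"), "unknown toy")
  # two acts on the same toy in one segment set a single bit
  s2 <- dyad_series(data.frame(toy = "cow",
                               agent = c("toddler", "parent"),
                               act = "handle", segment = c(4, 4)),
                    n_segments = 6)
  expect_equal(sum(occupancy(s2, "cow")), 1L)
})

test_that("cluster detection follows the minimum-two-adjacent-segments rule", {
  s <- table1_series()
  expect_equal(find_clusters(occupancy(s, "hippo")), 3L)
  expect_equal(find_clusters(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)),
               c(2L, 3L))
  expect_equal(find_clusters(c(TRUE, FALSE, TRUE, FALSE, TRUE)), integer(0))
  expect_equal(find_clusters(logical(0)), integer(0))
})

test_that("cluster statistics aggregate per category as constructed", {
  # every topic toy has exactly one length-3 run
  toys <- sprintf("T%d", 1:5)
  ev <- data.frame(toy = rep(toys, each = 3), agent = "toddler",
                   act = "handle",
                   segment = as.integer(outer(1:3, (0:4) * 4, "+")),
                   stringsAsFactors = FALSE)
  s <- dyad_series(ev, n_segments = 30)
  pt <- partition_topics(s)
  cs <- cluster_stats(s, pt)
  expect_equal(cs$n_clusters[cs$category == "topic"], 1)
  expect_equal(cs$mean_run_length[cs$category == "topic"], 3)
  expect_equal(cs$n_clusters[cs$category == "comment"], 0)
  cs_tot <- cluster_stats(s, pt, aggregate = "total")
  expect_equal(cs_tot$n_clusters[cs_tot$category == "topic"], 5)
})

test_that("label permutation preserves all frequency structure exactly", {
  set.seed(21)
  for (i in 1:10) {
    s <- rand_series(60)
    p <- permute_series(s)
    expect_equal(nrow(p$events), nrow(s$events))
    expect_equal(table(p$events$toy), table(s$events$toy))
    expect_equal(table(p$events$segment), table(s$events$segment))
    expect_identical(p$events[c("agent", "act", "segment")],
                     s$events[c("agent", "act", "segment")])
  }
  # single-toy series: permutation is the identity
  s1 <- make_series("only", 1:5, n_segments = 10)
  expect_identical(permute_series(s1)$events, s1$events)
})

test_that("sampled permutation distribution matches exhaustive enumeration on 6 events", {
  s <- table1_series()
  # exhaustive: all distinct assignments of {hippo x4, bucket, giraffe}
  # over the 6 slots, scored by total cluster count
  asg <- distinct_assignments(s$events$toy)
  expect_length(asg, 30L)
  score <- function(toys) {
    sc <- playnet:::series_codes(s)
    rn <- playnet:::runs_by_toy(match(toys, s$toy_universe), sc$segment)
    length(rn$len)
  }
  exact <- table(vapply(asg, score, numeric(1))) / length(asg)

  set.seed(31)
  n_draw <- 10000
  sc <- playnet:::series_codes(s)
  grp <- (sc$slot - 1L) * sc$n_segments + sc$segment
  draws <- vapply(seq_len(n_draw), function(i) {
    p <- playnet:::shuffle_toys(sc$toy, grp, length(sc$universe), FALSE)
    length(playnet:::runs_by_toy(p, sc$segment)$len)
  }, numeric(1))
  obs <- table(factor(draws, levels = names(exact)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(exact)))
  expect_gt(gof$p.value, 0.01)
})

test_that("permutation ensembles are reproducible and flag invariant statistics", {
  set.seed(1)
  s <- rand_series(60)
  e1 <- permutation_baseline(s, c("n_clusters", "total_events"),
                             n_perms = 50, seed = 9)
  e2 <- permutation_baseline(s, c("n_clusters", "total_events"),
                             n_perms = 50, seed = 9)
  expect_identical(e1$values, e2$values)
  expect_equal(e1$sd[["total_events"]], 0)
  expect_error(permutation_baseline(s, "entropy"), "unknown statistic")
})

test_that("quartile profile matches hand arithmetic on a 12-segment series", {
  # 12 segments -> quartiles of 3 segments each.
  # topics: {A} (k = 1 forced via k = 1), comments: {B, C}
  ev <- data.frame(
    toy = c("A", "A", "B", "A", "C", "A", "B", "C", "A"),
    agent = "toddler", act = "handle",
    segment = c(1, 2, 3, 4, 6, 7, 8, 11, 12),
    stringsAsFactors = FALSE)
  s <- dyad_series(ev, n_segments = 12)
  pt <- partition_topics(s, k = 1)
  qp <- quartile_profile(s, pt)
  tab <- qp$table
  # per-quartile selections: q1 = {A,A,B}, q2 = {A,C}, q3 = {A,B,C}? no:
  # segments 1-3|4-6|7-9|10-12 -> q1 {A,A,B}, q2 {A,C}, q3 {A,B}, q4 {C,A}
  top <- tab[tab$category == "topic", ]
  com <- tab[tab$category == "comment", ]
  expect_equal(top$proportion, c(2 / 3, 1 / 2, 1 / 2, 1 / 2))
  expect_equal(com$proportion, c(1 / 3, 1 / 2, 1 / 2, 1 / 2))
  # normalization: topics / 5, comments / number of comment toys (2)
  expect_equal(top$normalized_frequency, top$proportion / 5)
  expect_equal(com$normalized_frequency, com$proportion / 2)
})

test_that("121 segments split 30/30/30/31 and degenerate profiles behave", {
  s <- simulate_dyad(generator_params(), seed = 3)
  pt <- partition_topics(s)
  qp <- quartile_profile(s, pt)
  expect_equal(qp$boundaries$to - qp$boundaries$from + 1L,
               c(30L, 30L, 30L, 31L))
  # all topic events in quartile 1 -> zeros in quartiles 2-4
  ev <- data.frame(toy = "A", agent = "toddler", act = "handle",
                   segment = 1:5, stringsAsFactors = FALSE)
  s2 <- dyad_series(ev, n_segments = 40)
  qp2 <- quartile_profile(s2, partition_topics(s2, k = 1))
  top2 <- qp2$table[qp2$table$category == "topic", ]
  expect_equal(top2$normalized_frequency[2:4], rep(0, 3))
})

test_that("cross-recurrence on the worked example gives lags -5, -5, -10, -10", {
  s <- table1_series()
  cr <- cross_recurrence(s, partition_topics(s))
  expect_equal(sort(cr$lags$lag_s), c(-10, -10, -5, -5))
  expect_equal(cr$proportion_positive, 0)
  expect_equal(cr$n_pairs, 4L)
})

test_that("same-segment selections give lag zero and role swap negates lags", {
  s0 <- dyad_series(data.frame(toy = "cow",
                               agent = c("toddler", "parent"),
                               act = "handle", segment = c(7, 7)),
                    n_segments = 10)
  expect_equal(cross_recurrence(s0)$lags$lag_s, 0)

  set.seed(17)
  s <- rand_series(50)
  sw <- s
  sw$events$agent <- ifelse(s$events$agent == "toddler", "parent", "toddler")
  sw$events$act <- "handle"  # parent talk has no toddler counterpart
  sw$events <- unique(sw$events)
  s_h <- s
  s_h$events$act <- "handle"
  s_h$events <- unique(s_h$events)
  a <- cross_recurrence(s_h)$lags$lag_s
  b <- cross_recurrence(sw)$lags$lag_s
  expect_equal(sort(a), sort(-b))
})

test_that("lag multiset size is the sum over toys of toddler x parent event counts", {
  set.seed(23)
  for (i in 1:10) {
    s <- rand_series(50)
    cr <- cross_recurrence(s)
    ev <- s$events
    expected <- sum(vapply(unique(ev$toy), function(ty) {
      sum(ev$toy == ty & ev$agent == "toddler") *
        sum(ev$toy == ty & ev$agent == "parent")
    }, numeric(1)))
    expect_equal(cr$n_pairs, expected)
  }
  # no shared toys -> empty profile, not an error
  s2 <- dyad_series(data.frame(toy = c("a", "b"),
                               agent = c("toddler", "parent"),
                               act = "handle", segment = c(1, 2)),
                    n_segments = 5)
  cr2 <- cross_recurrence(s2)
  expect_equal(cr2$n_pairs, 0L)
  expect_true(is.na(cr2$proportion_positive))
})
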