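test_that("rank-frequency of the worked example is 4/6, 1/6, 1/6", {
  s <- table1_series()
  rf <- rank_frequency(behaviour_stream(s, "all"))
  expect_equal(rf$toy[1], "hippo")
  expect_equal(rf$proportion, c(4, 1, 1) / 6)
  expect_equal(rf$rank, 1:3)
  # tie between bucket (first selected at segment 10) and giraffe (11):
  # earlier first selection wins rank 2
  expect_equal(rf$toy[2:3], c("bucket", "giraffe"))
})

test_that("uniform counts give uniform proportions and proportions sum to 1", {
  s <- make_series(letters[1:4], c(1, 3, 5, 7), n_segments = 10)
  rf <- rank_frequency(behaviour_stream(s, "all"))
  expect_equal(rf$proportion, rep(1 / 4, 4))
  set.seed(3)
  for (i in 1:10) {
    rf <- rank_frequency(behaviour_stream(rand_series(40), "all"))
    expect_equal(sum(rf$proportion), 1)
    expect_true(all(diff(rf$count) <= 0))
  }
})

test_that("an empty stream yields a flagged empty table, not an error", {
  s <- make_series("a", 1, n_segments = 5)
  st <- behaviour_stream(s, "parent_talk")
  rf <- rank_frequency(st)
  expect_equal(nrow(rf), 0L)
  expect_true(attr(rf, "empty"))
})

test_that("comparing a stream with itself gives rho 1 and Wilcoxon p 1", {
  s <- table1_series()
  a <- behaviour_stream(s, "all")
  cmp <- compare_streams(a, a)
  expect_equal(cmp$spearman_rho, 1)
  expect_equal(cmp$wilcoxon_V, 0)
  expect_equal(cmp$wilcoxon_p, 1)
})

test_that("the distribution test ignores toy identity", {
  # relabelling toys leaves the rank-aligned frequency vectors identical,
  # so all Wilcoxon differences are zero even though rho is generally not 1
  set.seed(8)
  s <- rand_series(60, n_toys = 6)
  a <- behaviour_stream(s, "all")
  b <- a
  perm <- sample(names(a$counts))
  b$counts <- stats::setNames(a$counts, perm)[names(a$counts)]
  b$first_segment <- stats::setNames(a$first_segment, perm)[names(a$counts)]
  cmp <- compare_streams(a, b)
  expect_equal(cmp$wilcoxon_V, 0)
  expect_equal(cmp$wilcoxon_p, 1)
  expect_lt(cmp$spearman_rho, 1)
})

test_that("spearman matches a brute-force rank-then-pearson computation", {
  a_counts <- c(p = 10L, q = 4L, r = 4L, s = 1L, t = 0L)
  b_counts <- c(p = 7L, q = 6L, r = 1L, s = 2L, t = 1L)
  mk <- function(cnt) {
    structure(list(behaviour = "all", counts = cnt,
                   proportions = cnt / sum(cnt), total = sum(cnt),
                   first_segment = seq_along(cnt), dyad_id = "x"),
              class = "behaviour_stream")
  }
  cmp <- compare_streams(mk(a_counts), mk(b_counts))
  expect_equal(cmp$spearman_rho,
               stats::cor(rank(a_counts), rank(b_counts)))
})

test_that("mismatched universes are an argument error", {
  s1 <- make_series(letters[1:3], 1:3, n_segments = 5, pad_universe_to = 3)
  s2 <- make_series(letters[4:6], 1:3, n_segments = 5, pad_universe_to = 3)
  expect_error(compare_streams(behaviour_stream(s1, "all"),
                               behaviour_stream(s2, "all")),
               "universe")
})

test_that("topic partition takes the top-k toys with the stated share", {
  cnt <- c(A = 10L, B = 8L, C = 5L, D = 4L, E = 3L, F = 2L, G = 1L)
  ev <- data.frame(toy = rep(names(cnt), cnt), agent = "toddler",
                   act = "handle",
                   segment = seq_len(sum(cnt)), stringsAsFactors = FALSE)
  s <- dyad_series(ev, n_segments = 40)
  pt <- partition_topics(s)
  expect_setequal(pt$topics, c("A", "B", "C", "D", "E"))
  expect_setequal(pt$comments, c("F", "G"))
  expect_equal(pt$topic_share, 30 / 33)
})

test_that("fewer than k selected toys makes them all topics", {
  s <- make_series(c("a", "b", "c"), 1:3, n_segments = 10)
  pt <- partition_topics(s)
  expect_setequal(pt$topics, c("a", "b", "c"))
  expect_length(pt$comments, 0L)
  expect_equal(pt$topic_share, 1)
})

test_that("boundary ties resolve by first selection then lexicographically, invariant to row order", {
  # E and F tie at the rank-5 boundary; F is selected earlier
  ev <- data.frame(
    toy = c(rep("A", 5), rep("B", 4), rep("C", 4), rep("D", 4),
            "F", "F", "F", "E", "E", "E"),
    agent = "toddler", act = "handle",
    segment = c(1:5, 6:9, 10:13, 14:17, 18, 19, 20, 21, 22, 23),
    stringsAsFactors = FALSE)
  s <- dyad_series(ev, n_segments = 30)
  pt <- partition_topics(s)
  expect_true("F" %in% pt$topics)
  expect_true("E" %in% pt$comments)
  set.seed(5)
  for (i in 1:10) {
    s2 <- dyad_series(ev[sample.int(nrow(ev)), ], n_segments = 30)
    expect_identical(partition_topics(s2)$topics, pt$topics)
  }
  # equal first segments: lexicographic toy id decides
  ev2 <- ev
  ev2$segment[ev2$toy == "E"] <- c(18, 19, 20)
  ev2$segment[ev2$toy == "F"] <- c(18, 19, 20)
  pt2 <- partition_topics(dyad_series(ev2, n_segments = 30))
  expect_true("E" %in% pt2$topics)
})

test_that("topics are never under-represented relative to uniform", {
  set.seed(13)
  for (i in 1:20) {
    s <- rand_series(60, n_toys = 10)
    pt <- partition_topics(s)
    n_sel <- length(pt$topics) + length(pt$comments)
    expect_gte(pt$topic_share, length(pt$topics) / n_sel - 1e-12)
  }
})
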