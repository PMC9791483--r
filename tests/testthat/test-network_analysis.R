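test_that("the worked example yields exactly the 12 transition pairs", {
  s <- table1_series()
  p <- enumerate_pairs(s)
  expect_equal(nrow(p), 12L)
  expect_equal(sum(p$kind == "S"), 4L)
  expect_equal(sum(p$kind == "D"), 8L)
  expect_true(all(p$toy_a[p$kind == "S"] == "hippo"))
  # composition: 3 within segment n, 6 across n->n+1, 1 within n+1,
  # 2 across n+1->n+2
  within_n <- p$segment_a == 10 & p$segment_b == 10
  expect_equal(sum(within_n), 3L)
  expect_equal(sum(p$segment_a == 10 & p$segment_b == 11), 6L)
  expect_equal(sum(p$segment_a == 11 & p$segment_b == 11), 1L)
  expect_equal(sum(p$segment_a == 11 & p$segment_b == 12), 2L)
})

test_that("one event yields no pairs", {
  s <- make_series("a", 3, n_segments = 5)
  expect_equal(nrow(enumerate_pairs(s)), 0L)
})

test_that("pair count closed form matches the brute-force double loop", {
  set.seed(41)
  for (i in 1:100) {
    s <- rand_series(sample(2:80, 1), n_toys = 6,
                     n_segments = sample(5:40, 1))
    segs <- s$events$segment
    k <- tabulate(segs, s$n_segments)
    closed <- sum(choose(k, 2)) +
      sum(k[-length(k)] * k[-1])
    expect_equal(nrow(enumerate_pairs(s)), closed)
    expect_equal(closed, bf_pair_count(segs))
  }
})

test_that("network weights accumulate the worked-example pairs by kind", {
  s <- table1_series()
  net <- build_network(enumerate_pairs(s))
  expect_equal(net$s_weight[["hippo"]], 4)
  expect_equal(net$d_weight["bucket", "hippo"], 3)
  expect_equal(net$d_weight["bucket", "giraffe"], 1)
  expect_equal(net$d_weight["hippo", "giraffe"], 4)
  # conservation: S total + D total = |pairs|
  expect_equal(sum(net$s_weight) + sum(net$d_weight) / 2, 12)
  expect_equal(net$total_pairs, 12)
  # empty pairs -> empty network
  empty <- build_network(enumerate_pairs(make_series("a", 1,
                                                     n_segments = 3)))
  expect_length(empty$nodes, 0L)
})

test_that("triangle and path graphs give the textbook node measures", {
  s <- table1_series()
  net <- node_measures(build_network(enumerate_pairs(s)),
                       clustering = "binary")
  m <- net$measures
  expect_equal(m$degree, rep(2, 3))
  expect_equal(m$clustering_coefficient, rep(1, 3))
  expect_equal(m$betweenness, rep(0, 3))
  expect_equal(m$s_strength[m$toy == "hippo"], 4)
  expect_equal(m$d_strength[m$toy == "hippo"], 7)

  # path A - B - C: only B lies between the others
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 1
  W["B", "C"] <- W["C", "B"] <- 2
  pnet <- node_measures(build_network(weights = W), clustering = "binary")
  expect_equal(pnet$measures$betweenness, c(0, 1, 0))
  expect_equal(pnet$measures$clustering_coefficient, c(0, 0, 0))
})

test_that("betweenness and clustering match brute force on exhaustive small graphs", {
  # all labeled graphs on 4 nodes (64) and a sample of larger ones
  for (code in 0:63) {
    A <- matrix(0L, 4, 4)
    A[upper.tri(A)] <- as.integer(intToBits(code)[1:6])
    A <- A + t(A)
    dimnames(A) <- list(letters[1:4], letters[1:4])
    net <- node_measures(build_network(weights = A), clustering = "binary")
    expect_equal(net$measures$betweenness, bf_betweenness(A))
    expect_equal(net$measures$clustering_coefficient, bf_clustering(A))
  }
})

test_that("betweenness and clustering match brute force on graphs up to 7 nodes", {
  set.seed(51)
  for (n in 5:7) {
    for (rep in 1:40) {
      A <- rand_connected_graph(n, p = stats::runif(1, 0.25, 0.7))
      dimnames(A) <- list(letters[1:n], letters[1:n])
      net <- node_measures(build_network(weights = A), clustering = "binary")
      expect_equal(net$measures$betweenness, bf_betweenness(A),
                   tolerance = 1e-10)
      expect_equal(net$measures$clustering_coefficient, bf_clustering(A))
    }
  }
})

test_that("weighted clustering agrees with a hand computation", {
  # triangle with weights 1, 2, 4; max weight 4
  W <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  W["x", "y"] <- W["y", "x"] <- 1
  W["y", "z"] <- W["z", "y"] <- 2
  W["x", "z"] <- W["z", "x"] <- 4
  net <- node_measures(build_network(weights = W), clustering = "onnela")
  tri <- (1 / 4 * 2 / 4 * 4 / 4)^(1 / 3)
  expect_equal(net$measures$clustering_coefficient, rep(tri, 3))
})

test_that("random networks average transitions exactly on a tiny instance", {
  # 3 toys over 3 segments; exhaustive mean over all distinct assignments
  ev <- data.frame(toy = c("a", "a", "b", "c"), agent = "toddler",
                   act = "handle", segment = c(1, 2, 2, 3),
                   stringsAsFactors = FALSE)
  s <- dyad_series(ev, n_segments = 4, toy_universe = c("a", "b", "c"))
  asg <- distinct_assignments(s$events$toy)
  expect_length(asg, 12L)
  # the engine redraws shuffles that duplicate an event tuple, so the
  # exhaustive reference excludes assignments giving two same-toy events in
  # the same (agent, act, segment) slot
  valid <- vapply(asg, function(toys) {
    key <- paste(toys, s$events$agent, s$events$act, s$events$segment)
    anyDuplicated(key) == 0L
  }, logical(1))
  asg <- asg[valid]
  expect_length(asg, 10L)
  pairs_of <- function(toys) {
    s2 <- s
    s2$events$toy <- toys
    net <- build_network(enumerate_pairs(s2), nodes = c("a", "b", "c"))
    W <- net$d_weight
    diag(W) <- net$s_weight
    W
  }
  exact <- Reduce(`+`, lapply(asg, pairs_of)) / length(asg)

  ens <- permutation_baseline(s, "transition_matrix", n_perms = 20000,
                              seed = 77)
  got <- ens$mean_transition_matrix[c("a", "b", "c"), c("a", "b", "c")]
  expect_lt(max(abs(got - exact)), 0.03)

  rn <- random_network(s, ens)
  expect_equal(sum(rn$s_weight) + sum(rn$d_weight) / 2,
               build_network(enumerate_pairs(s))$total_pairs,
               tolerance = 1e-10)
})

test_that("single-toy series has identical observed and random networks", {
  s <- make_series("only", c(1, 2, 3, 5), n_segments = 6)
  obs <- build_network(enumerate_pairs(s), nodes = "only")
  ens <- permutation_baseline(s, "transition_matrix", n_perms = 50, seed = 3)
  rn <- random_network(s, ens)
  expect_equal(rn$s_weight, obs$s_weight)
  expect_equal(rn$d_weight, obs$d_weight)
})

test_that("a missing transition matrix is an argument error", {
  s <- table1_series()
  ens <- permutation_baseline(s, "n_clusters", n_perms = 10, seed = 1)
  expect_error(random_network(s, ens), "transition matrix")
})

test_that("total pair count is invariant under label permutation", {
  set.seed(61)
  for (i in 1:10) {
    s <- rand_series(50)
    expect_equal(nrow(enumerate_pairs(permute_series(s))),
                 nrow(enumerate_pairs(s)))
  }
})

test_that("network export round-trips through edge list and graphml", {
  s <- table1_series()
  net <- node_measures(build_network(enumerate_pairs(s)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  export_network(net, f1, "edgelist")
  el <- read.csv(f1)
  expect_equal(sum(el$weight), 12)
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f2, "graphml")
  g <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
})
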