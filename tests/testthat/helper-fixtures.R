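# Shared fixtures and independent brute-force oracles.

# The six-event worked example: three 5-s segments of dyadic play where the
# toddler handles the bucket then the hippo, the parent handles the hippo
# and talks about it, and a giraffe appears in passing.
table1_events <- function(n = 10L) {
  data.frame(
    toy = c("bucket", "hippo", "hippo", "hippo", "giraffe", "hippo"),
    agent = c("toddler", "parent", "parent", "toddler", "parent", "toddler"),
    act = c("handle", "handle", "talk", "handle", "handle", "handle"),
    segment = c(n, n, n, n + 1L, n + 1L, n + 2L),
    stringsAsFactors = FALSE)
}

table1_series <- function(n = 10L, ...) {
  dyad_series(table1_events(n), dyad_id = "worked", ...)
}

# quick builder: one toddler-handle event per (toy, segment)
make_series <- function(toys, segments, agents = "toddler", acts = "handle",
                        ...) {
  k <- max(length(toys), length(segments), length(agents), length(acts))
  dyad_series(data.frame(toy = rep_len(toys, k),
                         agent = rep_len(agents, k),
                         act = rep_len(acts, k),
                         segment = rep_len(segments, k),
                         stringsAsFactors = FALSE), ...)
}

# random valid event table for property tests
rand_series <- function(n_events = 60L, n_toys = 8L, n_segments = 40L,
                        dyad_id = "rand") {
  beh <- sample(3L, n_events, replace = TRUE)
  ev <- data.frame(
    toy = sample(sprintf("t%02d", seq_len(n_toys)), n_events, replace = TRUE),
    agent = c("toddler", "parent", "parent")[beh],
    act = c("handle", "handle", "talk")[beh],
    segment = sample.int(n_segments, n_events, replace = TRUE),
    stringsAsFactors = FALSE)
  suppressWarnings(dyad_series(ev, dyad_id = dyad_id,
                               n_segments = n_segments))
}

# all observed same-toy run lengths of a series (singletons included)
runs_lengths_all <- function(s, min_run = 1L) {
  toys <- unique(s$events$toy)
  unlist(lapply(toys, function(ty) find_clusters(occupancy(s, ty), min_run)))
}

# ---- brute-force network oracles ------------------------------------------

# all shortest paths between two nodes by exhaustive DFS over simple paths
bf_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  best <- list(len = Inf, paths = list())
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1L
      if (len < best$len) best <<- list(len = len, paths = list(path))
      else if (len == best$len) best$paths[[length(best$paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= best$len) return(invisible())
    for (w in which(A[v, ] > 0)) if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  best
}

# betweenness by exhaustive shortest-path enumeration: raw counts, endpoints
# excluded, multiple shortest paths contributing fractionally
bf_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    sp <- bf_shortest_paths(A, s, t)
    np <- length(sp$paths)
    if (np == 0L) next
    for (p in sp$paths) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / np
    }
  }
  btw
}

# classic local clustering: closed neighbour pairs / possible pairs
bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    closed <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      if (A[nb[a], nb[b]] > 0) closed <- closed + 1L
    }
    closed / choose(k, 2)
  }, numeric(1))
}

# brute-force close-in-time pair count: double loop over events
bf_pair_count <- function(segments) {
  n <- length(segments)
  cnt <- 0L
  if (n < 2L) return(0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(segments[i] - segments[j]) <= 1L) cnt <- cnt + 1L
  }
  cnt
}

# random connected undirected graph on n nodes (adjacency matrix)
rand_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- stats::rbinom(length(up), 1L, p)
    A <- A + t(A)
    # connectivity via reachability
    reach <- (diag(n) + A) %*% (diag(n) + A)
    for (i in seq_len(n)) reach <- (reach %*% (diag(n) + A)) > 0
    if (all(reach > 0)) return(A)
  }
}

# all distinct label assignments of a toy multiset over event slots
distinct_assignments <- function(toys) {
  uniq <- unique(toys)
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (u in unique(remaining)) {
      idx <- match(u, remaining)
      rec(c(prefix, u), remaining[-idx])
    }
  }
  rec(character(0), sort(toys))
  out
}

# ---- brute-force within-subject ANOVA oracle ------------------------------

# hand-computed sums of squares for a two-factor fully within design
bf_rm_anova <- function(y, s, A, B) {
  s <- factor(s); A <- factor(A); B <- factor(B)
  ns <- nlevels(s); na <- nlevels(A); nb <- nlevels(B)
  m <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mS <- tapply(y, s, mean)
  mAB <- tapply(y, list(A, B), mean)
  mSA <- tapply(y, list(s, A), mean)
  mSB <- tapply(y, list(s, B), mean)

  ss_A <- ns * nb * sum((mA - m)^2); df_A <- na - 1
  ss_SA <- nb * sum((mSA - outer(mS, mA, "+") + m)^2)
  df_SA <- (na - 1) * (ns - 1)
  ss_B <- ns * na * sum((mB - m)^2); df_B <- nb - 1
  ss_SB <- na * sum((mSB - outer(mS, mB, "+") + m)^2)
  df_SB <- (nb - 1) * (ns - 1)
  ss_AB <- ns * sum((mAB - outer(mA, mB, "+") + m)^2)
  df_AB <- (na - 1) * (nb - 1)
  resid <- y
  for (i in seq_along(y)) {
    si <- as.character(s[i]); ai <- as.character(A[i])
    bi <- as.character(B[i])
    resid[i] <- y[i] - mSA[si, ai] - mSB[si, bi] -
      mAB[ai, bi] + mA[ai] + mB[bi] + mS[si] - m
  }
  ss_SAB <- sum(resid^2); df_SAB <- (na - 1) * (nb - 1) * (ns - 1)

  data.frame(
    effect = c("A", "B", "A:B"),
    F = c((ss_A / df_A) / (ss_SA / df_SA),
          (ss_B / df_B) / (ss_SB / df_SB),
          (ss_AB / df_AB) / (ss_SAB / df_SAB)),
    df1 = c(df_A, df_B, df_AB),
    df2 = c(df_SA, df_SB, df_SAB),
    stringsAsFactors = FALSE)
}
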