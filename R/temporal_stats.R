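#' Per-segment occupancy of one toy
#'
#' Collapses a dyad's events for one toy into a boolean vector over the
#' segment grid: `TRUE` where the toy received at least one selection act by
#' any agent in that segment. Cluster statistics count runs of occupied
#' segments, not numbers of acts within a segment.
#'
#' @param series a [dyad_series].
#' @param toy a toy id from the series' universe.
#' @return Logical vector of length `n_segments`.
#' @export
occupancy <- function(series, toy) {
  stopifnot(inherits(series, "dyad_series"))
  if (!toy %in% series$toy_universe) {
    stop("unknown toy: ", toy)
  }
  occ <- rep(FALSE, series$n_segments)
  occ[series$events$segment[series$events$toy == toy]] <- TRUE
  occ
}

#' Run lengths of occupancy clusters
#'
#' A cluster is a maximal run of at least `min_run` consecutive occupied
#' segments (default 2: a single occupied segment is not a cluster).
#'
#' @param occ logical occupancy vector (see [occupancy()]).
#' @param min_run minimum run length that counts as a cluster (default 2).
#' @return Integer vector of run lengths (in segments; multiply by 5 for
#'   seconds), one element per cluster, in temporal order.
#' @export
find_clusters <- function(occ, min_run = 2L) {
  r <- rle(as.logical(occ))
  len <- r$lengths[r$values]
  as.integer(len[len >= min_run])
}

# ---- internal integer-coded engine ----------------------------------------

# integer codes for the hot loops: toy index, behaviour slot, segment
series_codes <- function(series) {
  ev <- series$events
  uni <- series$toy_universe
  beh <- paste(ev$agent, ev$act, sep = "_")
  list(toy = match(ev$toy, uni),
       slot = match(beh, BEHAVIOURS),
       segment = ev$segment,
       universe = uni,
       n_segments = series$n_segments,
       n = nrow(ev))
}

# run lengths per toy for an integer-coded assignment;
# returns list(toy = run toy index, len = run length), runs >= min_run.
# a single radix sort on the flat (toy, segment) key keeps this fast inside
# the permutation loop.
runs_by_toy <- function(toy, segment, min_run = 2L) {
  n <- length(toy)
  if (n == 0L) return(list(toy = integer(0), len = integer(0)))
  M <- max(segment) + 2L
  key <- sort.int((toy - 1L) * M + segment, method = "radix")
  key <- key[c(TRUE, key[-1L] != key[-n])]          # dedupe (toy, segment)
  m <- length(key)
  # consecutive occupied segments of one toy differ by exactly 1 in the key
  newrun <- c(TRUE, key[-1L] != key[-m] + 1L)
  rid <- cumsum(newrun)
  len <- tabulate(rid)
  rt <- (key[newrun] - 1L) %/% M + 1L
  ok <- len >= min_run
  list(toy = rt[ok], len = as.integer(len[ok]))
}

# topic/comment cluster summary from integer-coded events
cluster_core <- function(toy, segment, topic_ids, comment_ids,
                         min_run = 2L, aggregate = "per_toy") {
  rn <- runs_by_toy(toy, segment, min_run)
  is_t <- rn$toy %in% topic_ids
  is_c <- rn$toy %in% comment_ids
  nt <- sum(is_t); nc <- sum(is_c)
  div_t <- if (aggregate == "per_toy") max(length(topic_ids), 1L) else 1L
  div_c <- if (aggregate == "per_toy") max(length(comment_ids), 1L) else 1L
  c(n_clusters_topic = nt / div_t,
    n_clusters_comment = nc / div_c,
    run_length_topic = if (nt > 0L) mean(rn$len[is_t]) else NA_real_,
    run_length_comment = if (nc > 0L) mean(rn$len[is_c]) else NA_real_)
}

# quartile boundaries: equal floor(n/4) bins, remainder to the last
quartile_of <- function(segment, n_segments) {
  base <- n_segments %/% 4L
  q <- pmin((segment - 1L) %/% base + 1L, 4L)
  q
}

quartile_core <- function(toy, segment, topic_ids, comment_ids, n_segments) {
  q <- quartile_of(segment, n_segments)
  tot <- tabulate(q, 4L)
  qt <- tabulate(q[toy %in% topic_ids], 4L)
  qc <- tabulate(q[toy %in% comment_ids], 4L)
  div_c <- max(length(comment_ids), 1L)
  pt <- ifelse(tot > 0L, qt / tot, 0) / 5
  pc <- ifelse(tot > 0L, qc / tot, 0) / div_c
  stats::setNames(c(pt, pc),
                  c(paste0("q", 1:4, "_topic"), paste0("q", 1:4, "_comment")))
}

# precomputed close-in-time event index pairs (same or adjacent segment);
# depends only on the fixed (agent, act, segment) scaffold
pair_indices <- function(segment) {
  idx <- split(seq_along(segment), segment)
  segs <- as.integer(names(idx))
  ia <- integer(0); ib <- integer(0)
  for (j in seq_along(segs)) {
    w <- idx[[j]]
    k <- length(w)
    if (k >= 2L) {
      cmb <- utils::combn(w, 2L)
      ia <- c(ia, cmb[1L, ]); ib <- c(ib, cmb[2L, ])
    }
    nx <- match(segs[j] + 1L, segs)
    if (!is.na(nx)) {
      w2 <- idx[[nx]]
      ia <- c(ia, rep(w, each = length(w2)))
      ib <- c(ib, rep(w2, times = length(w)))
    }
  }
  list(a = ia, b = ib)
}

# upper-triangle (incl. diagonal) pair-count accumulation as a flat code
pair_codes <- function(toy_a, toy_b, n_toys) {
  lo <- pmin(toy_a, toy_b); hi <- pmax(toy_a, toy_b)
  (lo - 1L) * n_toys + hi
}

# one frequency-preserving shuffle of the integer toy labels; the
# (agent, act, segment) scaffold is fixed. grp codes the scaffold slot of
# each event; with check = TRUE a shuffle duplicating an event tuple is
# rejected and redrawn.
shuffle_toys <- function(toy, grp, n_toys, check, max_tries = 10000L) {
  n <- length(toy)
  for (i in seq_len(max_tries)) {
    p <- toy[sample.int(n)]
    if (!check || anyDuplicated((grp - 1) * n_toys + p) == 0L) return(p)
  }
  # collision-free draws are evidently vanishingly rare for this label
  # multiset; fall back to the unconstrained shuffle
  p
}

# decide once, per series, whether tuple-collision rejection is feasible:
# under heavily skewed label multisets collision-free shuffles can be
# vanishingly rare, in which case labels are shuffled over event slots
# unconditionally (frequencies, per-segment counts and event count are
# still exactly preserved; duplicate tuples are carried as slot events)
collision_mode <- function(toy, grp, n_toys, trial = 100L) {
  if (anyDuplicated(grp) == 0L) return(FALSE)
  n <- length(toy)
  for (i in seq_len(trial)) {
    p <- toy[sample.int(n)]
    if (anyDuplicated((grp - 1) * n_toys + p) == 0L) return(TRUE)
  }
  FALSE
}

# ---------------------------------------------------------------------------

#' Topic/Comment cluster statistics for one dyad
#'
#' Counts occupancy clusters (runs of >= `min_run` consecutive segments with
#' at least one selection of the same toy) and their run lengths, separately
#' for the high-frequency Topic toys and the low-frequency Comment toys.
#'
#' With `aggregate = "per_toy"` (default) the cluster count is the mean
#' number of clusters per toy in the category (denominator: number of Topic
#' toys, respectively number of Comment toys referenced by the dyad); with
#' `"total"` it is the per-dyad total. Mean run length is averaged over the
#' clusters of the category and is `NA` when the category has none. Lowering
#' `min_run` to 1 includes singleton runs, an alternative averaging basis.
#'
#' @param series a [dyad_series].
#' @param partition a [topic_partition] derived from the same series.
#' @param aggregate `"per_toy"` or `"total"`.
#' @param min_run minimum run length counted as a cluster (default 2).
#' @return Data frame with one row per category: `category`, `n_clusters`,
#'   `mean_run_length`, `n_toys`; attribute `run_lengths` holds the raw run
#'   lengths per category.
#' @export
cluster_stats <- function(series, partition,
                          aggregate = c("per_toy", "total"), min_run = 2L) {
  stopifnot(inherits(series, "dyad_series"),
            inherits(partition, "topic_partition"))
  aggregate <- match.arg(aggregate)
  sc <- series_codes(series)
  tid <- match(partition$topics, sc$universe)
  cid <- match(partition$comments, sc$universe)
  rn <- runs_by_toy(sc$toy, sc$segment, min_run)
  v <- cluster_core(sc$toy, sc$segment, tid, cid, min_run, aggregate)
  out <- data.frame(
    category = c("topic", "comment"),
    n_clusters = c(v[["n_clusters_topic"]], v[["n_clusters_comment"]]),
    mean_run_length = c(v[["run_length_topic"]], v[["run_length_comment"]]),
    n_toys = c(length(tid), length(cid)),
    stringsAsFactors = FALSE)
  attr(out, "run_lengths") <- list(
    topic = rn$len[rn$toy %in% tid],
    comment = rn$len[rn$toy %in% cid])
  out
}

#' Frequency-preserving permutation of a dyad series
#'
#' Randomly reassigns the toy labels over the event list while holding the
#' (agent, act, segment) scaffold fixed: the per-toy aggregate frequencies,
#' the per-segment event counts and the total event count are exactly
#' preserved, but all temporal dependence between selections of the same toy
#' is destroyed. Shuffles that would duplicate an event tuple are rejected
#' and redrawn; when the label multiset is so skewed that collision-free
#' shuffles are vanishingly rare (no success in 100 trial draws), labels are
#' shuffled unconditionally and any duplicate tuples collapsed. Uses the
#' current RNG state; call `set.seed()` for reproducibility.
#'
#' @param series a non-empty [dyad_series].
#' @return A [dyad_series] with permuted toy labels.
#' @export
permute_series <- function(series) {
  stopifnot(inherits(series, "dyad_series"))
  sc <- series_codes(series)
  if (sc$n == 0L) stop("cannot permute an empty series")
  grp <- (sc$slot - 1L) * sc$n_segments + sc$segment
  check <- collision_mode(sc$toy, grp, length(sc$universe))
  p <- shuffle_toys(sc$toy, grp, length(sc$universe), check)
  ev <- series$events
  ev$toy <- sc$universe[p]
  suppressWarnings(
    dyad_series(ev, dyad_id = series$dyad_id, n_segments = series$n_segments,
                toy_universe = series$toy_universe))
}

#' Permutation baseline for dyad-level statistics
#'
#' Builds the random baseline the temporal and network analyses are compared
#' against: `n_perms` frequency-preserving label permutations of the series
#' (see [permute_series()]), with the requested statistics evaluated on each.
#' The ensemble instantiates the null hypothesis that a statistic's value
#' emerges solely from the per-toy selection frequencies.
#'
#' Registered statistics: `"n_clusters"` and `"run_length"` (per
#' Topic/Comment category, see [cluster_stats()]), `"quartile_profile"`
#' (8 normalised values, see [quartile_profile()]), `"total_events"` (a
#' permutation-invariant check quantity), and `"transition_matrix"` (mean
#' close-in-time pair counts per toy pair, the basis of the permutation-mean
#' random network, see [random_network()]).
#'
#' @param series a non-empty [dyad_series].
#' @param statistics character vector of registered statistic names.
#' @param n_perms number of permutations (default 10000).
#' @param seed RNG seed for the ensemble.
#' @param partition a [topic_partition]; computed from the series when
#'   `NULL`.
#' @param min_run,aggregate passed to the cluster statistic.
#' @return Object of class `permutation_ensemble`: `values` (matrix, one row
#'   per permutation), `mean`, `sd`, `mean_transition_matrix` (when
#'   requested; symmetric toy-by-toy matrix whose diagonal holds same-toy
#'   pair means), `n_perms`, `seed`.
#' @export
permutation_baseline <- function(series,
                                 statistics = c("n_clusters", "run_length"),
                                 n_perms = 10000L, seed = NULL,
                                 partition = NULL, min_run = 2L,
                                 aggregate = "per_toy") {
  stopifnot(inherits(series, "dyad_series"))
  known <- c("n_clusters", "run_length", "quartile_profile",
             "transition_matrix", "total_events")
  bad <- setdiff(statistics, known)
  if (length(bad) > 0L) {
    stop("unknown statistic(s): ", paste(bad, collapse = ", "),
         " (registered: ", paste(known, collapse = ", "), ")")
  }
  sc <- series_codes(series)
  if (sc$n == 0L) stop("cannot permute an empty series")
  if (is.null(partition)) partition <- partition_topics(series)
  tid <- match(partition$topics, sc$universe)
  cid <- match(partition$comments, sc$universe)
  U <- length(sc$universe)

  grp <- (sc$slot - 1L) * sc$n_segments + sc$segment
  want_cluster <- any(c("n_clusters", "run_length") %in% statistics)
  want_quart <- "quartile_profile" %in% statistics
  want_trans <- "transition_matrix" %in% statistics
  want_total <- "total_events" %in% statistics
  if (want_trans) {
    pi_ <- pair_indices(sc$segment)
    acc <- numeric(U * U)
  }

  cols <- character(0)
  if (want_cluster) cols <- c(cols, "n_clusters_topic", "n_clusters_comment",
                              "run_length_topic", "run_length_comment")
  if (want_quart) cols <- c(cols, paste0("q", 1:4, "_topic"),
                            paste0("q", 1:4, "_comment"))
  if (want_total) cols <- c(cols, "total_events")
  vals <- matrix(NA_real_, nrow = n_perms, ncol = length(cols),
                 dimnames = list(NULL, cols))

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  check <- collision_mode(sc$toy, grp, U)

  for (i in seq_len(n_perms)) {
    p <- shuffle_toys(sc$toy, grp, U, check)
    if (want_cluster) {
      vals[i, 1:4] <- cluster_core(p, sc$segment, tid, cid, min_run,
                                   aggregate)
    }
    if (want_quart) {
      vals[i, paste0("q", rep(1:4, 2), rep(c("_topic", "_comment"),
                                           each = 4))] <-
        quartile_core(p, sc$segment, tid, cid, sc$n_segments)
    }
    if (want_total) vals[i, "total_events"] <- length(p)
    if (want_trans) {
      cd <- pair_codes(p[pi_$a], p[pi_$b], U)
      acc <- acc + tabulate(cd, U * U)
    }
  }

  mtm <- NULL
  if (want_trans) {
    # acc is indexed by the flat code (lo-1)*U + hi with lo <= hi, so the
    # byrow matrix holds the unordered mean pair count at [lo, hi]
    full <- matrix(acc / n_perms, nrow = U, ncol = U, byrow = TRUE)
    mtm <- full + t(full)
    diag(mtm) <- diag(full)
    dimnames(mtm) <- list(sc$universe, sc$universe)
  }

  structure(
    list(statistics = statistics, n_perms = as.integer(n_perms), seed = seed,
         values = vals,
         mean = if (ncol(vals) > 0L) colMeans(vals, na.rm = TRUE) else NULL,
         sd = if (ncol(vals) > 0L) apply(vals, 2L, stats::sd, na.rm = TRUE)
              else NULL,
         mean_transition_matrix = mtm,
         partition = partition, dyad_id = series$dyad_id),
    class = "permutation_ensemble"
  )
}

#' @export
print.permutation_ensemble <- function(x, ...) {
  cat("<permutation_ensemble> ", x$dyad_id, ": ", x$n_perms,
      " permutations of {", paste(x$statistics, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' Quartile recurrence profile
#'
#' Splits the session into four quartiles (equal numbers of segments, the
#' last absorbing the remainder: 30/30/30/31 for 121 segments) and scores
#' each quartile by the normalised selection frequency of each category: the
#' within-quartile proportion of selections going to Topic toys divided by
#' the number of Topic toys (5), and the proportion going to Comment toys
#' divided by the number of Comment toys referenced by the dyad. A flat
#' Topic profile means the main-theme toys recur throughout the session.
#'
#' @param series a [dyad_series] with at least 4 segments.
#' @param partition a [topic_partition] for the series.
#' @return List of class `quartile_profile`: `table` (data frame quartile x
#'   category with `proportion` and `normalized_frequency`),
#'   `topic_rank_profile` (5 x 4 matrix: per-quartile proportion of Topic
#'   selections by Topic rank), and `boundaries`.
#' @export
quartile_profile <- function(series, partition) {
  stopifnot(inherits(series, "dyad_series"),
            inherits(partition, "topic_partition"),
            series$n_segments >= 4L)
  sc <- series_codes(series)
  tid <- match(partition$topics, sc$universe)
  cid <- match(partition$comments, sc$universe)
  q <- quartile_of(sc$segment, sc$n_segments)
  tot <- tabulate(q, 4L)
  qt <- tabulate(q[sc$toy %in% tid], 4L)
  qc <- tabulate(q[sc$toy %in% cid], 4L)
  div_c <- max(length(cid), 1L)
  prop_t <- ifelse(tot > 0L, qt / tot, 0)
  prop_c <- ifelse(tot > 0L, qc / tot, 0)
  tab <- data.frame(
    quartile = rep(1:4, times = 2L),
    category = rep(c("topic", "comment"), each = 4L),
    n_selections = c(qt, qc),
    proportion = c(prop_t, prop_c),
    normalized_frequency = c(prop_t / 5, prop_c / div_c),
    stringsAsFactors = FALSE)

  rank_prof <- matrix(0, nrow = length(tid), ncol = 4L,
                      dimnames = list(partition$topics,
                                      paste0("q", 1:4)))
  for (r in seq_along(tid)) {
    cnt <- tabulate(q[sc$toy == tid[r]], 4L)
    rank_prof[r, ] <- ifelse(qt > 0L, cnt / qt, 0)
  }

  base <- series$n_segments %/% 4L
  bounds <- data.frame(quartile = 1:4,
                       from = (0:3) * base + 1L,
                       to = c(1:3 * base, series$n_segments))
  structure(list(table = tab, topic_rank_profile = rank_prof,
                 boundaries = bounds, dyad_id = series$dyad_id),
            class = "quartile_profile")
}

#' Cross-recurrence lag profile between toddler and parent
#'
#' For every pair of a toddler handling event and a parent event (handling
#' or talk) on the same toy, computes the signed lag in seconds:
#' `(parent segment - toddler segment) * 5`, so positive lags mean the
#' toddler selected the toy first and zero means both acted within the same
#' 5-s segment. All pairs over the whole session are counted, not only the
#' nearest ones. `proportion_positive` is the share of positive lags among
#' the nonzero lags (lead/lag comparison; simultaneous selections are
#' uninformative about who led).
#'
#' @param series a [dyad_series].
#' @param partition optional [topic_partition] for per-category summaries.
#' @return List of class `lag_profile`: `lags` (data frame toy, category,
#'   toddler_segment, parent_segment, lag_s), `n_pairs`,
#'   `proportion_positive`, `mean_lag` (named: overall, topic, comment). A
#'   series with no shared toys yields an empty profile with `n_pairs = 0`,
#'   not an error.
#' @export
cross_recurrence <- function(series, partition = NULL) {
  stopifnot(inherits(series, "dyad_series"))
  ev <- series$events
  tod <- ev[ev$agent == "toddler", , drop = FALSE]
  par <- ev[ev$agent == "parent", , drop = FALSE]
  shared <- intersect(unique(tod$toy), unique(par$toy))
  rows <- lapply(shared, function(ty) {
    ts <- tod$segment[tod$toy == ty]
    ps <- par$segment[par$toy == ty]
    data.frame(toy = ty,
               toddler_segment = rep(ts, times = length(ps)),
               parent_segment = rep(ps, each = length(ts)),
               stringsAsFactors = FALSE)
  })
  lags <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(toy = character(0), toddler_segment = integer(0),
               parent_segment = integer(0))
  lags$lag_s <- (lags$parent_segment - lags$toddler_segment) * 5
  lags$category <- if (!is.null(partition)) {
    as.character(toy_category(lags$toy, partition))
  } else rep(NA_character_, nrow(lags))
  nz <- lags$lag_s[lags$lag_s != 0]
  mean_by <- function(cat) {
    v <- lags$lag_s[!is.na(lags$category) & lags$category == cat]
    if (length(v) > 0L) mean(v) else NA_real_
  }
  structure(
    list(lags = lags, n_pairs = nrow(lags),
         proportion_positive = if (length(nz) > 0L) mean(nz > 0) else
           NA_real_,
         mean_lag = c(overall = if (nrow(lags) > 0L) mean(lags$lag_s) else
                        NA_real_,
                      topic = mean_by("topic"),
                      comment = mean_by("comment")),
         dyad_id = series$dyad_id),
    class = "lag_profile"
  )
}

#' @export
print.lag_profile <- function(x, ...) {
  cat("<lag_profile> ", x$dyad_id, ": ", x$n_pairs, " pairs, ",
      sprintf("%.0f%% positive, mean lag %.1f s",
              100 * x$proportion_positive, x$mean_lag[["overall"]]),
      "\n", sep = "")
  invisible(x)
}
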