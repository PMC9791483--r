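#' Rank-frequency table of a behaviour stream
#'
#' Orders a stream's per-toy counts by decreasing frequency, the standard
#' Zipf-style view of selection data. Ties are broken deterministically by
#' earlier first selection within the stream, then lexicographically by toy
#' id, so the table is invariant to input row order.
#'
#' @param stream a [behaviour_stream].
#' @param drop_zero drop never-selected toys (default `TRUE`; set `FALSE` to
#'   keep the full universe with trailing zero rows).
#' @return A data frame of class `rank_frequency_table` with columns `toy`,
#'   `count`, `proportion`, `rank` (1 = most frequent); counts non-increasing
#'   in rank and proportions summing to 1. An empty stream yields a zero-row
#'   table with attribute `empty = TRUE` rather than an error.
#' @export
rank_frequency <- function(stream, drop_zero = TRUE) {
  stopifnot(inherits(stream, "behaviour_stream"))
  counts <- stream$counts
  fs <- stream$first_segment
  ord <- order(-counts, fs, names(counts))
  counts <- counts[ord]
  if (drop_zero) counts <- counts[counts > 0L]
  total <- sum(counts)
  out <- data.frame(toy = names(counts), count = as.integer(counts),
                    proportion = if (total > 0L) as.numeric(counts / total)
                                 else rep(0, length(counts)),
                    rank = seq_along(counts), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "behaviour") <- stream$behaviour
  attr(out, "empty") <- total == 0L
  class(out) <- c("rank_frequency_table", "data.frame")
  out
}

#' Compare two behaviour streams of one dyad
#'
#' Two within-dyad tests over the full toy universe. (1) A paired Wilcoxon
#' signed-rank test on the rank-aligned frequency vectors (the count at rank
#' i in stream a against the count at rank i in stream b, ranks padded with
#' zeros to the universe size): this compares the shapes of the two
#' frequency distributions while ignoring toy identity, so relabelling the
#' toys of one stream leaves it unchanged. (2) Spearman rank correlation on
#' the per-toy counts over the full universe including zero-count toys
#' (average ranks for ties), measuring whether the two behaviours favour the
#' same toys.
#'
#' When the rank-aligned vectors are identical all paired differences are
#' zero and the signed-rank statistic is reported as `V = 0`, `p = 1` by
#' convention.
#'
#' @param a,b [behaviour_stream]s over the same toy universe.
#' @return List of class `stream_comparison`: `wilcoxon_V`, `wilcoxon_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
compare_streams <- function(a, b) {
  stopifnot(inherits(a, "behaviour_stream"), inherits(b, "behaviour_stream"))
  if (!identical(sort(names(a$counts)), sort(names(b$counts)))) {
    stop("streams must share the same toy universe")
  }
  va <- sort(as.numeric(a$counts), decreasing = TRUE)
  vb <- sort(as.numeric(b$counts[names(a$counts)]), decreasing = TRUE)
  d <- va - vb
  if (all(d == 0)) {
    V <- 0; pV <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(va, vb, paired = TRUE,
                                              exact = FALSE))
    V <- unname(wt$statistic); pV <- wt$p.value
  }
  ct <- suppressWarnings(
    stats::cor.test(as.numeric(a$counts),
                    as.numeric(b$counts[names(a$counts)]),
                    method = "spearman", exact = FALSE))
  structure(
    list(wilcoxon_V = V, wilcoxon_p = pV,
         spearman_rho = unname(ct$estimate), spearman_p = ct$p.value),
    class = "stream_comparison"
  )
}

#' @export
print.stream_comparison <- function(x, ...) {
  cat(sprintf("<stream_comparison> V = %.1f (p = %.3g), rho = %.3f (p = %.3g)\n",
              x$wilcoxon_V, x$wilcoxon_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Partition a dyad's toys into Topics and Comments
#'
#' Splits the selected toys into the `k` most frequently selected
#' ("Topics", the high-frequency given content; default five) and the
#' remaining selected toys ("Comments", the low-frequency new content),
#' using the aggregate count over all three behaviours. Rank ties at the
#' Topic boundary are broken by earlier first selection, then
#' lexicographically, so the partition is deterministic and invariant to
#' input row order. If fewer than `k` toys were selected, all are Topics.
#'
#' @param series a [dyad_series] with at least one event.
#' @param k number of Topic toys (default 5).
#' @return List of class `topic_partition`: `dyad_id`, `topics`, `comments`
#'   (both character), `topic_share` (fraction of all selections going to
#'   Topic toys), `k`, `counts` (aggregate per-toy counts of selected toys).
#' @export
partition_topics <- function(series, k = 5L) {
  stopifnot(inherits(series, "dyad_series"))
  if (nrow(series$events) == 0L) stop("series has no events")
  rf <- rank_frequency(behaviour_stream(series, "all"), drop_zero = TRUE)
  k_eff <- min(as.integer(k), nrow(rf))
  topics <- rf$toy[seq_len(k_eff)]
  comments <- rf$toy[-seq_len(k_eff)]
  if (k_eff == nrow(rf)) comments <- character(0)
  structure(
    list(dyad_id = series$dyad_id, topics = topics, comments = comments,
         topic_share = sum(rf$count[seq_len(k_eff)]) / sum(rf$count),
         k = as.integer(k),
         counts = stats::setNames(rf$count, rf$toy)),
    class = "topic_partition"
  )
}

#' @export
print.topic_partition <- function(x, ...) {
  cat("<topic_partition> ", x$dyad_id, ": topics {",
      paste(x$topics, collapse = ", "), "}, ", length(x$comments),
      " comment toys, topic share ", sprintf("%.2f", x$topic_share),
      "\n", sep = "")
  invisible(x)
}

# category factor ("topic"/"comment"/NA) for a vector of toys
toy_category <- function(toys, partition) {
  out <- rep(NA_character_, length(toys))
  out[toys %in% partition$topics] <- "topic"
  out[toys %in% partition$comments] <- "comment"
  factor(out, levels = c("topic", "comment"))
}
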