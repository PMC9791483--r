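#' Enumerate close-in-time transition pairs
#'
#' Lists every unordered pair of distinct selection events that occurred in
#' the same segment (co-occurring) or in adjacent segments: the transitions
#' that feed the dyad network. A pair is an S transition when both events
#' select the same toy (a self-loop) and a D transition when they select
#' different toys; pair identity is non-directional, so giraffe-hippo and
#' hippo-giraffe are the same edge.
#'
#' @param series a [dyad_series].
#' @return Data frame with one row per pair: `toy_a`, `toy_b`, `kind`
#'   (`"S"`/`"D"`), and provenance columns `segment_a`, `segment_b`,
#'   `agent_a`, `act_a`, `agent_b`, `act_b` (event a is the earlier, or
#'   co-occurring first in canonical order). For `k_t` events per segment the
#'   pair count is `sum_t C(k_t, 2) + sum_t k_t * k_{t+1}`.
#' @export
enumerate_pairs <- function(series) {
  stopifnot(inherits(series, "dyad_series"))
  ev <- series$events
  if (nrow(ev) < 2L) {
    return(data.frame(toy_a = character(0), toy_b = character(0),
                      kind = character(0), segment_a = integer(0),
                      segment_b = integer(0), agent_a = character(0),
                      act_a = character(0), agent_b = character(0),
                      act_b = character(0), stringsAsFactors = FALSE))
  }
  pi_ <- pair_indices(ev$segment)
  a <- pi_$a; b <- pi_$b
  out <- data.frame(
    toy_a = ev$toy[a], toy_b = ev$toy[b],
    kind = ifelse(ev$toy[a] == ev$toy[b], "S", "D"),
    segment_a = ev$segment[a], segment_b = ev$segment[b],
    agent_a = ev$agent[a], act_a = ev$act[a],
    agent_b = ev$agent[b], act_b = ev$act[b],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a dyad transition network
#'
#' Accumulates transition pairs into a weighted undirected toy graph: S
#' pairs add to per-node self-loop weights (`s_weight`), D pairs to the
#' symmetric edge-weight matrix (`d_weight`). The total weight equals the
#' number of pairs.
#'
#' @param pairs pair table from [enumerate_pairs()] (one dyad), or a
#'   precomputed weight matrix via `weights =`.
#' @param nodes node set; defaults to the toys appearing in `pairs`.
#' @param partition optional [topic_partition] used to tag nodes as
#'   topic/comment.
#' @param weights optional symmetric numeric matrix (diagonal = S weights)
#'   used instead of `pairs`, e.g. permutation-mean transition counts.
#' @return Object of class `dyad_network`: `nodes`, `s_weight` (named),
#'   `d_weight` (symmetric matrix, zero diagonal), `category` (factor per
#'   node or `NA`), `total_pairs`.
#' @export
build_network <- function(pairs = NULL, nodes = NULL, partition = NULL,
                          weights = NULL) {
  if (is.null(weights)) {
    stopifnot(is.data.frame(pairs))
    if (is.null(nodes)) nodes <- sort(unique(c(pairs$toy_a, pairs$toy_b)))
    n <- length(nodes)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(pairs) > 0L) {
      ia <- match(pairs$toy_a, nodes); ib <- match(pairs$toy_b, nodes)
      lo <- pmin(ia, ib); hi <- pmax(ia, ib)
      cnt <- tabulate((lo - 1L) * n + hi, n * n)
      full <- matrix(cnt, n, n, byrow = TRUE)
      W <- full + t(full)
      diag(W) <- diag(full)
      dimnames(W) <- list(nodes, nodes)
    }
  } else {
    stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
    if (is.null(nodes)) nodes <- rownames(weights)
    W <- weights[nodes, nodes, drop = FALSE]
  }
  s_w <- diag(W)
  d_w <- W
  diag(d_w) <- 0
  cat_ <- if (!is.null(partition)) toy_category(nodes, partition) else
    factor(rep(NA_character_, length(nodes)), levels = c("topic", "comment"))
  structure(
    list(nodes = nodes, s_weight = stats::setNames(s_w, nodes),
         d_weight = d_w, category = cat_,
         total_pairs = sum(s_w) + sum(d_w) / 2),
    class = "dyad_network"
  )
}

#' @export
print.dyad_network <- function(x, ...) {
  cat("<dyad_network> ", length(x$nodes), " nodes, ",
      sum(x$d_weight > 0) / 2, " D edges, total pair weight ",
      format(x$total_pairs), "\n", sep = "")
  invisible(x)
}

# Onnela-style weighted local clustering: geometric-mean triangle intensity
# over weights normalised by the maximum weight; igraph implements the
# Barrat variant, which degenerates to the binary coefficient on
# near-complete graphs, so this one is computed directly.
onnela_clustering <- function(W, threshold = 0) {
  A <- (W > threshold) * 1
  k <- rowSums(A)
  mx <- max(W)
  if (mx <= 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3) * A
  tri <- diag(Wh %*% Wh %*% Wh)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(cc)
}

binary_clustering <- function(A) {
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)
  as.numeric(ifelse(k >= 2, tri / (k * (k - 1)), 0))
}

#' Node-level network measures
#'
#' Fills in per-node measures of a [dyad_network]: `s_strength` (self-loop
#' weight: repeated same-toy transitions), `d_strength` (summed weight of
#' incident different-toy edges), `degree` (number of distinct neighbours on
#' the binarized D graph; self-loops never count), `betweenness` (number of
#' shortest paths between other node pairs passing through the node,
#' computed on the unweighted binarized D graph, endpoints excluded,
#' multiple shortest paths contributing fractionally), and
#' `clustering_coefficient` (transitivity of the node's neighbourhood).
#'
#' The default clustering coefficient is the Onnela weighted form (triangle
#' intensity over weights normalised by the maximum weight), which remains
#' informative on the dense fractional-weight random networks;
#' `clustering = "binary"` gives the classic unweighted local coefficient
#' (triangles over possible triangles among neighbours). Global transitivity
#' of the binarized graph is attached as attribute `transitivity`.
#'
#' @param net a [dyad_network].
#' @param clustering `"onnela"` (default) or `"binary"`.
#' @param threshold edge-presence threshold for binarization: an edge exists
#'   iff its weight exceeds `threshold` (default 0).
#' @return The network with a `measures` data frame added: `toy`,
#'   `category`, `s_strength`, `d_strength`, `degree`, `betweenness`,
#'   `clustering_coefficient`.
#' @export
node_measures <- function(net, clustering = c("onnela", "binary"),
                          threshold = 0) {
  stopifnot(inherits(net, "dyad_network"))
  clustering <- match.arg(clustering)
  if (length(net$nodes) == 0L) stop("network is empty")
  W <- net$d_weight
  A <- (W > threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cc <- if (clustering == "onnela") onnela_clustering(W, threshold) else
    binary_clustering(A)
  net$measures <- data.frame(
    toy = net$nodes,
    category = as.character(net$category),
    s_strength = as.numeric(net$s_weight),
    d_strength = as.numeric(rowSums(W)),
    degree = as.numeric(rowSums(A)),
    betweenness = as.numeric(btw),
    clustering_coefficient = cc,
    stringsAsFactors = FALSE)
  attr(net$measures, "transitivity") <-
    igraph::transitivity(g, type = "global")
  net
}

#' Permutation-mean random network
#'
#' Builds the Random network of a dyad: edge weights are the mean transition
#' pair counts over the permutation ensemble (fractional), instantiating the
#' null that the observed network structure follows from toy-selection
#' frequencies alone. Measures are computed with the same conventions as for
#' the observed network.
#'
#' @param series the observed [dyad_series] (fixes the node set: its
#'   selected toys).
#' @param ensemble a [permutation_baseline()] result carrying
#'   `mean_transition_matrix` for this series.
#' @param partition optional [topic_partition] for node categories.
#' @return A [dyad_network] with fractional weights.
#' @export
random_network <- function(series, ensemble, partition = NULL) {
  stopifnot(inherits(series, "dyad_series"),
            inherits(ensemble, "permutation_ensemble"))
  if (is.null(ensemble$mean_transition_matrix)) {
    stop("ensemble does not carry a mean transition matrix; ",
         "request statistic \"transition_matrix\" in permutation_baseline()")
  }
  nodes <- selected_toys(series)
  build_network(weights = ensemble$mean_transition_matrix, nodes = nodes,
                partition = partition)
}

#' Export a network
#'
#' Writes a dyad network as an edge-list CSV (S self-loops included as
#' `toy_a == toy_b` rows) or as GraphML.
#'
#' @param net a [dyad_network].
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "dyad_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    n <- length(net$nodes)
    rows <- which(upper.tri(net$d_weight) & net$d_weight > 0, arr.ind = TRUE)
    df <- data.frame(
      toy_a = c(net$nodes[rows[, 1L]], net$nodes[net$s_weight > 0]),
      toy_b = c(net$nodes[rows[, 2L]], net$nodes[net$s_weight > 0]),
      kind = c(rep("D", nrow(rows)), rep("S", sum(net$s_weight > 0))),
      weight = c(net$d_weight[rows], net$s_weight[net$s_weight > 0]),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    W <- net$d_weight
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$s_weight <- as.numeric(net$s_weight)
    igraph::V(g)$category <- as.character(net$category)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
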