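#' Two-factor repeated-measures ANOVA
#'
#' Within-subject analysis of variance with two crossed within factors, the
#' design used for every Observed-vs-Random by Topic-vs-Comment contrast
#' (and, with a 4-level factor, for the quartile analysis). One value per
#' cell per subject is required. F ratios use the standard within-subject
#' error strata (each effect tested against its subject-by-effect
#' interaction); no sphericity correction is applied, which is exact for
#' 2-level factors.
#'
#' @param data data frame in long format.
#' @param value,subject,factor1,factor2 column names.
#' @return Data frame of class `anova_result` with one row per effect
#'   (`factor1`, `factor2`, interaction): `effect`, `F`, `df1`, `df2`, `p`.
#'   For a 2x2 design with n subjects each effect has `df1 = 1`,
#'   `df2 = n - 1`.
#' @export
rm_anova_2x2 <- function(data, value = "value", subject = "subject",
                         factor1 = "factor1", factor2 = "factor2") {
  stopifnot(is.data.frame(data))
  need <- c(value, subject, factor1, factor2)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stop("missing column(s): ",
                              paste(miss, collapse = ", "))
  d <- data.frame(y = as.numeric(data[[value]]),
                  s = factor(data[[subject]]),
                  A = factor(data[[factor1]]),
                  B = factor(data[[factor2]]))
  if (anyNA(d$y)) stop("missing cell values")
  tab <- table(d$s, d$A, d$B)
  if (any(tab != 1L)) {
    stop("design must have exactly one value per subject x cell ",
         "(complete crossed design)")
  }
  if (stats::var(d$y) == 0) {
    # degenerate all-constant design: no variation to partition
    out <- data.frame(
      effect = c(factor1, factor2, paste(factor1, factor2, sep = ":")),
      F = 0, df1 = c(nlevels(d$A) - 1L, nlevels(d$B) - 1L,
                     (nlevels(d$A) - 1L) * (nlevels(d$B) - 1L)),
      df2 = c(nlevels(d$A) - 1L, nlevels(d$B) - 1L,
              (nlevels(d$A) - 1L) * (nlevels(d$B) - 1L)) *
        (nlevels(d$s) - 1L),
      p = 1, stringsAsFactors = FALSE)
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tb <- sm[[stratum]][[1L]]
    i <- match(term, trimws(rownames(tb)))
    c(F = tb[i, "F value"], df1 = tb[i, "Df"],
      df2 = tb[trimws(rownames(tb)) == "Residuals", "Df"],
      p = tb[i, "Pr(>F)"])
  }
  eff <- rbind(pick("Error: s:A", "A"), pick("Error: s:B", "B"),
               pick("Error: s:A:B", "A:B"))
  out <- data.frame(
    effect = c(factor1, factor2, paste(factor1, factor2, sep = ":")),
    F = eff[, "F"], df1 = as.integer(eff[, "df1"]),
    df2 = as.integer(eff[, "df2"]), p = eff[, "p"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# mean/sd/range summary row, the paper-style reporting triple
summarise_vec <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
             max = NA_real_))
  }
  c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
}

#' Analyse one dyad
#'
#' Runs the full per-dyad analysis: Topic/Comment partition, behaviour
#' streams and their pairwise comparisons, observed cluster statistics, the
#' frequency-preserving permutation baseline (cluster, quartile and
#' transition statistics), quartile profiles, cross-recurrence lags, and
#' observed plus permutation-mean random networks with node measures.
#'
#' @param series a [dyad_series].
#' @param n_perms permutations for the baseline.
#' @param seed RNG seed for the permutation ensemble.
#' @param k_topics number of Topic toys.
#' @param min_run,aggregate cluster-statistic conventions, see
#'   [cluster_stats()].
#' @param clustering clustering-coefficient variant, see [node_measures()].
#' @return List with elements `series`, `partition`, `streams`,
#'   `comparisons`, `clusters_obs`, `ensemble`, `quartiles`, `crqa`,
#'   `network_obs`, `network_rand`.
#' @export
analyse_dyad <- function(series, n_perms = 1000L, seed = 1L, k_topics = 5L,
                         min_run = 2L, aggregate = "per_toy",
                         clustering = "onnela") {
  partition <- partition_topics(series, k = k_topics)
  streams <- lapply(stats::setNames(nm = c("all", BEHAVIOURS)),
                    function(b) behaviour_stream(series, b))
  pairs_cmp <- list(
    toddler_handle_vs_parent_handle =
      compare_streams(streams$toddler_handle, streams$parent_handle),
    parent_handle_vs_parent_talk =
      compare_streams(streams$parent_handle, streams$parent_talk),
    parent_talk_vs_toddler_handle =
      compare_streams(streams$parent_talk, streams$toddler_handle))
  clusters_obs <- cluster_stats(series, partition, aggregate = aggregate,
                                min_run = min_run)
  ens <- permutation_baseline(
    series,
    statistics = c("n_clusters", "run_length", "quartile_profile",
                   "transition_matrix"),
    n_perms = n_perms, seed = seed, partition = partition,
    min_run = min_run, aggregate = aggregate)
  quart <- quartile_profile(series, partition)
  crqa <- cross_recurrence(series, partition)
  net_obs <- node_measures(
    build_network(enumerate_pairs(series), nodes = selected_toys(series),
                  partition = partition),
    clustering = clustering)
  net_rand <- node_measures(random_network(series, ens, partition),
                            clustering = clustering)
  list(series = series, partition = partition, streams = streams,
       comparisons = pairs_cmp, clusters_obs = clusters_obs,
       ensemble = ens, quartiles = quart, crqa = crqa,
       network_obs = net_obs, network_rand = net_rand)
}

# per-dyad, per-network-type, per-category means of node measures
network_cells <- function(dyad_id, net, network_type) {
  m <- net$measures
  m <- m[!is.na(m$category), , drop = FALSE]
  out <- do.call(rbind, lapply(split(m, m$category), function(d) {
    data.frame(dyad = dyad_id, network = network_type,
               category = d$category[1L],
               s_strength = mean(d$s_strength),
               d_strength = mean(d$d_strength),
               degree = mean(d$degree),
               betweenness = mean(d$betweenness),
               clustering_coefficient = mean(d$clustering_coefficient),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the cohort pipeline
#'
#' Orchestrates the full analysis over a cohort of dyads: event model ->
#' frequency statistics -> temporal statistics and permutation baselines ->
#' networks -> within-subject contrasts. The cohort comes either from an
#' event table on disk or from the synthetic generator. Deterministic given
#' the configuration.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   `events_file` (path) or `simulate` (list with `n_dyads` and optional
#'   [generator_params()] arguments); `n_perms` (default 1000); `seed`
#'   (default 1); `k_topics` (default 5); `min_run` (default 2);
#'   `aggregate` (default `"per_toy"`); `clustering` (default `"onnela"`).
#' @param progress print per-dyad progress to stderr.
#' @return Object of class `cohort_report`: per-dyad tables
#'   (`engagement`, `stream_comparisons`, `clusters`, `quartiles`, `crqa`,
#'   `network`), `group_summaries`, `anovas`, `dyads` (the per-dyad analysis
#'   objects) and `metadata`.
#' @export
run_pipeline <- function(config = list(), progress = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  n_perms <- as.integer(config$n_perms %||% 1000L)
  seed <- as.integer(config$seed %||% 1L)
  k_topics <- as.integer(config$k_topics %||% 5L)
  min_run <- as.integer(config$min_run %||% 2L)
  aggregate <- config$aggregate %||% "per_toy"
  clustering <- config$clustering %||% "onnela"

  if (!is.null(config$events_file)) {
    cohort <- read_events(config$events_file)
  } else {
    sim <- config$simulate %||% list()
    n_dyads <- as.integer(sim$n_dyads %||% 32L)
    par_args <- sim[setdiff(names(sim), "n_dyads")]
    params <- do.call(generator_params, par_args)
    cohort <- simulate_cohort(n_dyads, params, seed = seed)
  }
  n_dyads <- length(cohort)
  perm_seeds <- (seed %% 1000000L) * 1000L + 500L + seq_len(n_dyads)

  dyads <- vector("list", n_dyads)
  names(dyads) <- names(cohort)
  for (i in seq_len(n_dyads)) {
    t0 <- Sys.time()
    dyads[[i]] <- tryCatch(
      analyse_dyad(cohort[[i]], n_perms = n_perms, seed = perm_seeds[i],
                   k_topics = k_topics, min_run = min_run,
                   aggregate = aggregate, clustering = clustering),
      error = function(e) {
        stop("dyad ", names(cohort)[i], ", stage analyse_dyad: ",
             conditionMessage(e), call. = FALSE)
      })
    if (progress) {
      message(sprintf("[%s] analysed in %.1fs", names(cohort)[i],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }

  engagement <- do.call(rbind, lapply(dyads, function(d) {
    s <- d$series
    occ <- length(unique(s$events$segment)) / s$n_segments
    uniq <- function(b) sum(d$streams[[b]]$counts > 0L)
    data.frame(dyad = s$dyad_id, n_events = nrow(s$events),
               prop_segments_selected = occ,
               unique_toys_toddler_handle = uniq("toddler_handle"),
               unique_toys_parent_handle = uniq("parent_handle"),
               unique_toys_parent_talk = uniq("parent_talk"),
               topic_share = d$partition$topic_share,
               stringsAsFactors = FALSE)
  }))

  stream_cmp <- do.call(rbind, lapply(dyads, function(d) {
    do.call(rbind, lapply(names(d$comparisons), function(nm) {
      cmp <- d$comparisons[[nm]]
      data.frame(dyad = d$series$dyad_id, comparison = nm,
                 wilcoxon_V = cmp$wilcoxon_V, wilcoxon_p = cmp$wilcoxon_p,
                 spearman_rho = cmp$spearman_rho,
                 spearman_p = cmp$spearman_p, stringsAsFactors = FALSE)
    }))
  }))

  clusters <- do.call(rbind, lapply(dyads, function(d) {
    obs <- d$clusters_obs
    em <- d$ensemble$mean
    rbind(
      data.frame(dyad = d$series$dyad_id, network = "observed",
                 category = obs$category, n_clusters = obs$n_clusters,
                 mean_run_length = obs$mean_run_length,
                 stringsAsFactors = FALSE),
      data.frame(dyad = d$series$dyad_id, network = "random",
                 category = c("topic", "comment"),
                 n_clusters = c(em[["n_clusters_topic"]],
                                em[["n_clusters_comment"]]),
                 mean_run_length = c(em[["run_length_topic"]],
                                     em[["run_length_comment"]]),
                 stringsAsFactors = FALSE))
  }))

  quart <- do.call(rbind, lapply(dyads, function(d) {
    cbind(dyad = d$series$dyad_id, d$quartiles$table,
          stringsAsFactors = FALSE)
  }))

  crqa <- do.call(rbind, lapply(dyads, function(d) {
    data.frame(dyad = d$series$dyad_id, n_pairs = d$crqa$n_pairs,
               proportion_positive = d$crqa$proportion_positive,
               mean_lag_s = d$crqa$mean_lag[["overall"]],
               mean_lag_topic_s = d$crqa$mean_lag[["topic"]],
               mean_lag_comment_s = d$crqa$mean_lag[["comment"]],
               stringsAsFactors = FALSE)
  }))

  network <- do.call(rbind, lapply(dyads, function(d) {
    rbind(network_cells(d$series$dyad_id, d$network_obs, "observed"),
          network_cells(d$series$dyad_id, d$network_rand, "random"))
  }))
  rownames(engagement) <- rownames(stream_cmp) <- rownames(clusters) <-
    rownames(quart) <- rownames(crqa) <- rownames(network) <- NULL

  anovas <- list()
  # drop dyads with a missing or incomplete cell (e.g. a dyad with no
  # comment toys, or no comment clusters at all); the contrast needs a
  # complete 2 x 2 within every retained dyad
  try_anova <- function(df, col, f1 = "network", f2 = "category") {
    df <- df[!is.na(df[[col]]), , drop = FALSE]
    n_cells <- length(unique(df[[f1]])) * length(unique(df[[f2]]))
    full <- table(df$dyad)
    keep <- names(full)[full == n_cells]
    d2 <- df[df$dyad %in% keep, , drop = FALSE]
    if (length(keep) < 2L || length(unique(d2[[f1]])) < 2L ||
        length(unique(d2[[f2]])) < 2L) {
      return(NULL)
    }
    res <- rm_anova_2x2(d2, value = col, subject = "dyad",
                        factor1 = f1, factor2 = f2)
    cbind(measure = col, res, n_dyads = length(keep),
          stringsAsFactors = FALSE)
  }
  anovas$n_clusters <- try_anova(clusters, "n_clusters")
  anovas$run_length <- try_anova(clusters, "mean_run_length")
  for (col in c("s_strength", "d_strength", "degree", "betweenness",
                "clustering_coefficient")) {
    anovas[[col]] <- try_anova(network, col)
  }
  quart$quartile_f <- factor(quart$quartile)
  anovas$quartile <- tryCatch(
    cbind(measure = "normalized_frequency",
          rm_anova_2x2(quart, value = "normalized_frequency",
                       subject = "dyad", factor1 = "category",
                       factor2 = "quartile_f"),
          n_dyads = length(unique(quart$dyad)),
          stringsAsFactors = FALSE),
    error = function(e) NULL)
  anova_tab <- do.call(rbind, anovas[!vapply(anovas, is.null, logical(1))])
  rownames(anova_tab) <- NULL

  group <- list(
    engagement = t(vapply(engagement[-1L], summarise_vec, numeric(4))),
    clusters = do.call(rbind, lapply(
      split(clusters, interaction(clusters$network, clusters$category)),
      function(d) c(n_clusters = summarise_vec(d$n_clusters),
                    run_length = summarise_vec(d$mean_run_length)))),
    spearman_rho = t(vapply(split(stream_cmp$spearman_rho,
                                  stream_cmp$comparison),
                            summarise_vec, numeric(4))),
    wilcoxon_V = t(vapply(split(stream_cmp$wilcoxon_V,
                                stream_cmp$comparison),
                          summarise_vec, numeric(4))),
    crqa = t(vapply(crqa[-1L], summarise_vec, numeric(4))))

  structure(
    list(engagement = engagement, stream_comparisons = stream_cmp,
         clusters = clusters, quartiles = quart, crqa = crqa,
         network = network, anovas = anova_tab, group_summaries = group,
         dyads = dyads,
         metadata = list(seed = seed, n_perms = n_perms,
                         k_topics = k_topics, min_run = min_run,
                         aggregate = aggregate, clustering = clustering,
                         n_dyads = n_dyads,
                         total_segments = sum(vapply(
                           dyads, function(d) d$series$n_segments,
                           numeric(1))))),
    class = "cohort_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", x$metadata$n_dyads, " dyads, ",
      x$metadata$n_perms, " permutations/dyad, seed ",
      x$metadata$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits the per-dyad tables as CSV and the group summaries, ANOVA table
#' and metadata as JSON. Group means are recomputed from the emitted
#' per-dyad tables at write time and checked against the stored summaries.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("engagement", "stream_comparisons", "clusters", "quartiles",
               "crqa", "network")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  # self-consistency: summaries must be recomputable from the emitted table
  re <- utils::read.csv(file.path(dir, "engagement.csv"))
  stopifnot(isTRUE(all.equal(
    unname(colMeans(re[-1L])),
    unname(report$group_summaries$engagement[, "mean"]),
    tolerance = 1e-8)))
  utils::write.csv(report$anovas, file.path(dir, "anovas.csv"),
                   row.names = FALSE)
  js <- list(metadata = report$metadata,
             group_summaries = lapply(report$group_summaries, function(m)
               as.data.frame(m)))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
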