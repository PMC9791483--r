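#' Parameters of the synthetic dyad generator
#'
#' Bundles and validates the knobs of [simulate_dyad()]. The generator is a
#' minimal "more-gets-more" mechanism: a reinforced urn over toys (selection
#' weight grows with past selection count), a persistent focal toy carrying
#' play across segments, occasional novelty draws of never-selected toys, and
#' parent acts coupled in time to the toddler's current toy. Defaults emulate
#' a standard session: 32 available toys, 121 five-second segments, event
#' rate chosen so roughly nine in ten segments contain at least one
#' selection, a skewed per-toy frequency distribution with the five
#' most-selected toys taking about half of all selections, bursty same-toy
#' runs and close-in-time partner coupling.
#'
#' @param n_toys number of toys available in the room (default 32).
#' @param n_segments number of 5-s segments (default 121).
#' @param events_per_segment_rate mean selection events per segment
#'   (Poisson; default 2.4, leaving ~9% of segments empty).
#' @param novelty_alpha urn weight mass assigned to the pool of
#'   never-selected toys (default 10); larger values broaden the toy
#'   repertoire.
#' @param reinforcement_gamma exponent on past selection counts in the urn
#'   weight (default 0.65, sublinear "more-gets-more"; 1 is the linear
#'   urn, which concentrates selections far more strongly than observed
#'   play).
#' @param persistence_rho probability that the focal toy carries over from
#'   the previous segment (default 0.6); drives bursty same-toy runs.
#' @param coupling_kappa probability that a parent act targets the toddler's
#'   current focal toy rather than an urn draw (default 0.5); drives
#'   close-in-time cross-recurrence at lags 0 to -5 s.
#' @param behaviour_probs probabilities that an event is toddler handling,
#'   parent handling, parent talk (normalised to sum 1).
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_toys = 32L, n_segments = 121L,
                             events_per_segment_rate = 2.4,
                             novelty_alpha = 10, reinforcement_gamma = 0.65,
                             persistence_rho = 0.6, coupling_kappa = 0.5,
                             behaviour_probs = c(toddler_handle = 0.4,
                                                 parent_handle = 0.33,
                                                 parent_talk = 0.37)) {
  n_toys <- as.integer(n_toys)
  n_segments <- as.integer(n_segments)
  stopifnot(n_toys >= 1L, n_segments >= 1L)
  if (!(events_per_segment_rate > 0)) {
    stop("events_per_segment_rate must be > 0")
  }
  for (p in c(persistence_rho, coupling_kappa)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("persistence_rho and coupling_kappa must be probabilities in [0, 1]")
    }
  }
  if (novelty_alpha < 0 || reinforcement_gamma < 0) {
    stop("novelty_alpha and reinforcement_gamma must be non-negative")
  }
  stopifnot(length(behaviour_probs) == 3L, all(behaviour_probs >= 0),
            sum(behaviour_probs) > 0)
  behaviour_probs <- behaviour_probs / sum(behaviour_probs)
  structure(
    list(n_toys = n_toys, n_segments = n_segments,
         events_per_segment_rate = events_per_segment_rate,
         novelty_alpha = novelty_alpha,
         reinforcement_gamma = reinforcement_gamma,
         persistence_rho = persistence_rho,
         coupling_kappa = coupling_kappa,
         behaviour_probs = behaviour_probs),
    class = "generator_params"
  )
}

# one reinforced-urn draw; counts: past selections per toy
urn_draw <- function(counts, alpha, gamma) {
  w <- ifelse(counts > 0, counts^gamma, 0)
  new_pool <- which(counts == 0)
  if (length(new_pool) > 0L && alpha > 0) {
    w[new_pool] <- alpha / length(new_pool)
  }
  if (sum(w) <= 0) w <- rep(1, length(counts))
  sample.int(length(counts), 1L, prob = w)
}

#' Simulate one dyad's play session
#'
#' Generates a [dyad_series] from the reinforced-urn mechanism described in
#' [generator_params()]. Per segment the event count is Poisson; each event
#' is assigned a behaviour; toddler handling targets the focal toy, which
#' persists across segments with probability `persistence_rho` and otherwise
#' is redrawn from the urn; parent acts copy the toddler's focal toy with
#' probability `coupling_kappa` and otherwise draw from the urn. Every
#' selection reinforces its toy's urn weight. Duplicate event tuples arising
#' within a segment are collapsed, as in coded data.
#'
#' @param params a [generator_params] object.
#' @param seed RNG seed (integer); the output is a pure function of
#'   `(params, seed)`.
#' @param dyad_id identifier for the generated dyad.
#' @param first_toy optionally force the initial focal toy (index or name).
#' @return A [dyad_series] over toys `toy01..toyNN`.
#' @export
simulate_dyad <- function(params = generator_params(), seed = 1L,
                          dyad_id = "sim", first_toy = NULL) {
  stopifnot(inherits(params, "generator_params"))
  toys <- sprintf("toy%02d", seq_len(params$n_toys))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))

  counts <- numeric(params$n_toys)
  focal <- if (is.null(first_toy)) {
    urn_draw(counts, params$novelty_alpha, params$reinforcement_gamma)
  } else if (is.character(first_toy)) {
    match(first_toy, toys)
  } else {
    as.integer(first_toy)
  }
  stopifnot(!is.na(focal), focal >= 1L, focal <= params$n_toys)

  beh_levels <- BEHAVIOURS
  rec_toy <- integer(0); rec_beh <- integer(0); rec_seg <- integer(0)
  for (t in seq_len(params$n_segments)) {
    if (t > 1L && stats::runif(1) > params$persistence_rho) {
      focal <- urn_draw(counts, params$novelty_alpha,
                        params$reinforcement_gamma)
    }
    k <- stats::rpois(1L, params$events_per_segment_rate)
    if (k == 0L) next
    beh <- sample.int(3L, k, replace = TRUE, prob = params$behaviour_probs)
    for (e in seq_len(k)) {
      if (beh[e] == 1L) {
        toy <- focal
      } else if (stats::runif(1) < params$coupling_kappa) {
        toy <- focal
      } else {
        toy <- urn_draw(counts, params$novelty_alpha,
                        params$reinforcement_gamma)
      }
      counts[toy] <- counts[toy] + 1
      rec_toy <- c(rec_toy, toy); rec_beh <- c(rec_beh, beh[e])
      rec_seg <- c(rec_seg, t)
    }
  }
  agent <- c("toddler", "parent", "parent")[rec_beh]
  act <- c("handle", "handle", "talk")[rec_beh]
  ev <- data.frame(toy = toys[rec_toy], agent = agent, act = act,
                   segment = rec_seg, stringsAsFactors = FALSE)
  suppressWarnings(
    dyad_series(ev, dyad_id = dyad_id, n_segments = params$n_segments,
                toy_universe = toys)
  )
}

#' Simulate a memoryless null dyad
#'
#' Draws selection events i.i.d. across segments from a fixed toy-frequency
#' distribution: no persistence, reinforcement or coupling, so every temporal
#' statistic matches its own permutation baseline up to Monte-Carlo error.
#' Instantiates the null hypothesis that temporal structure emerges solely
#' from the per-toy selection frequencies.
#'
#' @param freqs named numeric vector of per-toy probabilities (must sum to 1
#'   within 1e-8).
#' @param n_segments number of 5-s segments.
#' @param rate mean events per segment (Poisson).
#' @param seed RNG seed.
#' @param dyad_id identifier.
#' @param behaviour_probs event-wise behaviour split, as in
#'   [generator_params()].
#' @return A [dyad_series].
#' @export
simulate_null <- function(freqs, n_segments = 121L, rate = 2.4, seed = 1L,
                          dyad_id = "null",
                          behaviour_probs = c(0.4, 0.33, 0.37)) {
  stopifnot(is.numeric(freqs), length(freqs) >= 1L, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must sum to 1")
  }
  if (is.null(names(freqs))) {
    names(freqs) <- sprintf("toy%02d", seq_along(freqs))
  }
  stopifnot(rate >= 0)
  behaviour_probs <- behaviour_probs / sum(behaviour_probs)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))

  n_segments <- as.integer(n_segments)
  k <- stats::rpois(n_segments, rate)
  n <- sum(k)
  if (n == 0L) {
    return(dyad_series(
      data.frame(toy = character(0), agent = character(0),
                 act = character(0), segment = integer(0)),
      dyad_id = dyad_id, n_segments = n_segments,
      toy_universe = names(freqs)))
  }
  seg <- rep.int(seq_len(n_segments), k)
  toy <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  beh <- sample.int(3L, n, replace = TRUE, prob = behaviour_probs)
  ev <- data.frame(toy = toy,
                   agent = c("toddler", "parent", "parent")[beh],
                   act = c("handle", "handle", "talk")[beh],
                   segment = seg, stringsAsFactors = FALSE)
  suppressWarnings(
    dyad_series(ev, dyad_id = dyad_id, n_segments = n_segments,
                toy_universe = names(freqs))
  )
}

#' Simulate a cohort of dyads
#'
#' Convenience wrapper generating `n_dyads` independent sessions with
#' per-dyad seeds derived deterministically from `seed`.
#'
#' @param n_dyads number of dyads (default 32, a standard cohort).
#' @param params shared [generator_params].
#' @param seed master seed; dyad `i` uses `seed * 1000 + i` (kept within
#'   integer range).
#' @return Named list of [dyad_series].
#' @export
simulate_cohort <- function(n_dyads = 32L, params = generator_params(),
                            seed = 1L) {
  n_dyads <- as.integer(n_dyads)
  seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n_dyads)
  out <- lapply(seq_len(n_dyads), function(i) {
    simulate_dyad(params, seed = seeds[i],
                  dyad_id = sprintf("dyad%02d", i))
  })
  names(out) <- vapply(out, function(s) s$dyad_id, character(1))
  out
}

# save/restore the global RNG state so seeded simulators do not perturb the
# caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
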