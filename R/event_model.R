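#' @keywords internal
"_PACKAGE"

AGENTS <- c("toddler", "parent")
ACTS <- c("handle", "talk")
BEHAVIOURS <- c("toddler_handle", "parent_handle", "parent_talk")

#' Construct a dyad series
#'
#' A `dyad_series` holds one dyad's full play session: a deduplicated,
#' canonically ordered table of toy-selection events on a fixed grid of
#' 5-second segments. A selection event is one referential act on a toy --
#' toddler handling, parent handling, or parent talk about the toy -- and is
#' identified by the tuple (toy, agent, act, segment). Toddler talk is not a
#' coded act.
#'
#' @param events data frame with columns `toy` (character), `agent`
#'   (`"toddler"` or `"parent"`), `act` (`"handle"` or `"talk"`), `segment`
#'   (integer in `1:n_segments`).
#' @param dyad_id identifier for the dyad.
#' @param n_segments number of 5-s segments on the session grid. The default
#'   121 is the segment count of a standard 10-minute session as coded.
#' @param toy_universe character vector of available toys. Defaults to the
#'   observed toys padded with placeholder ids up to `pad_universe_to`, so
#'   that never-selected toys exist for full-universe rank correlations.
#' @param pad_universe_to minimum universe size when `toy_universe` is `NULL`
#'   (default 32, the size of the standard toy room).
#' @param dedupe if `TRUE` (default) duplicated event tuples are collapsed
#'   with a warning; if `FALSE` duplicates raise an error.
#'
#' @return An object of class `dyad_series`: a list with elements `dyad_id`,
#'   `n_segments`, `toy_universe` and `events` (canonically ordered by
#'   segment, agent, act, toy).
#' @export
dyad_series <- function(events, dyad_id = "dyad", n_segments = 121L,
                        toy_universe = NULL, pad_universe_to = 32L,
                        dedupe = TRUE) {
  stopifnot(is.data.frame(events))
  need <- c("toy", "agent", "act", "segment")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L) {
    stop("events is missing column(s): ", paste(miss, collapse = ", "))
  }
  events <- as.data.frame(events)[need]
  events$toy <- as.character(events$toy)
  events$agent <- as.character(events$agent)
  events$act <- as.character(events$act)
  events$segment <- as.integer(events$segment)
  n_segments <- as.integer(n_segments)
  stopifnot(length(n_segments) == 1L, n_segments >= 1L)

  if (nrow(events) > 0L) {
    bad_agent <- !events$agent %in% AGENTS
    if (any(bad_agent)) {
      stop("invalid agent value(s): ",
           paste(unique(events$agent[bad_agent]), collapse = ", "),
           " (row ", which(bad_agent)[1L], ")")
    }
    bad_act <- !events$act %in% ACTS
    if (any(bad_act)) {
      stop("invalid act value(s): ",
           paste(unique(events$act[bad_act]), collapse = ", "),
           " (row ", which(bad_act)[1L], ")")
    }
    tt <- events$agent == "toddler" & events$act == "talk"
    if (any(tt)) {
      stop("toddler talk is not a coded selection act (row ",
           which(tt)[1L], ")")
    }
    oob <- is.na(events$segment) | events$segment < 1L |
      events$segment > n_segments
    if (any(oob)) {
      stop("segment out of range 1..", n_segments,
           " (row ", which(oob)[1L], ")")
    }
    key <- paste(events$toy, events$agent, events$act, events$segment,
                 sep = "\r")
    if (anyDuplicated(key)) {
      if (!dedupe) stop("duplicated selection-event tuple(s)")
      ndup <- sum(duplicated(key))
      warning(ndup, " duplicated selection event(s) collapsed")
      events <- events[!duplicated(key), , drop = FALSE]
    }
    events <- events[order(events$segment, events$agent, events$act,
                           events$toy), , drop = FALSE]
    rownames(events) <- NULL
  }

  observed <- sort(unique(events$toy))
  if (is.null(toy_universe)) {
    toy_universe <- observed
    if (length(toy_universe) < pad_universe_to) {
      pad <- sprintf("unselected_%02d",
                     seq_len(pad_universe_to - length(toy_universe)))
      toy_universe <- c(toy_universe, pad)
    }
  } else {
    toy_universe <- as.character(toy_universe)
    extra <- setdiff(observed, toy_universe)
    if (length(extra) > 0L) {
      stop("event toy(s) outside toy_universe: ",
           paste(extra, collapse = ", "))
    }
  }

  structure(
    list(dyad_id = as.character(dyad_id), n_segments = n_segments,
         toy_universe = toy_universe, events = events),
    class = "dyad_series"
  )
}

#' @export
print.dyad_series <- function(x, ...) {
  cat("<dyad_series> ", x$dyad_id, ": ", nrow(x$events), " events, ",
      length(unique(x$events$toy)), "/", length(x$toy_universe),
      " toys, ", x$n_segments, " segments\n", sep = "")
  invisible(x)
}

#' Read selection-event tables
#'
#' Reads a delimited event table (CSV or TSV) with header columns
#' `dyad,segment,agent,act,toy` into one [dyad_series] per dyad. Rows
#' violating the coding rules (toddler talk, out-of-range segments) raise
#' validation errors naming the offending row; exact duplicate event tuples
#' are collapsed with a warning.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab` means tab, otherwise comma).
#' @param n_segments,toy_universe,pad_universe_to passed to [dyad_series].
#' @return A named list of `dyad_series`, one per dyad id (in order of first
#'   appearance).
#' @seealso [write_events()] for the inverse operation.
#' @export
read_events <- function(path, sep = NULL, n_segments = 121L,
                        toy_universe = NULL, pad_universe_to = 32L) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("dyad", "segment", "agent", "act", "toy")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("input file is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  seg <- suppressWarnings(as.integer(df$segment))
  if (anyNA(seg)) {
    stop("non-integer segment value (row ", which(is.na(seg))[1L], ")")
  }
  df$segment <- seg
  out <- lapply(split(df, factor(df$dyad, levels = unique(df$dyad))),
                function(d) {
                  dyad_series(d[c("toy", "agent", "act", "segment")],
                              dyad_id = d$dyad[1L], n_segments = n_segments,
                              toy_universe = toy_universe,
                              pad_universe_to = pad_universe_to)
                })
  out
}

#' Write selection-event tables
#'
#' Writes one or more [dyad_series] back to the standard delimited dialect
#' (`dyad,segment,agent,act,toy`). Reading the result with [read_events()]
#' reproduces the deduplicated, canonically ordered table.
#'
#' @param series a `dyad_series` or list of them.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
write_events <- function(series, path, sep = ",") {
  if (inherits(series, "dyad_series")) series <- list(series)
  tabs <- lapply(series, function(s) {
    ev <- s$events
    data.frame(dyad = rep(s$dyad_id, nrow(ev)), segment = ev$segment,
               agent = ev$agent, act = ev$act, toy = ev$toy,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, tabs)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-toy selection counts for one behaviour stream
#'
#' Tallies a dyad's selection events of one behaviour (`toddler_handle`,
#' `parent_handle`, `parent_talk`) or of all three (`"all"`) per toy, over the
#' full toy universe (zero-count toys retained), with proportions normalised
#' by the stream total. The `"all"` stream is the aggregate count ignoring who
#' selected and how, the basis of the Topic/Comment analyses.
#'
#' @param series a [dyad_series].
#' @param behaviour one of `"all"`, `"toddler_handle"`, `"parent_handle"`,
#'   `"parent_talk"`.
#' @return An object of class `behaviour_stream`: list with `behaviour`,
#'   `counts` (named integer over the toy universe), `proportions`, `total`,
#'   and `first_segment` (segment of first selection per toy, `Inf` when
#'   never selected in this stream; used for deterministic tie-breaking).
#' @export
behaviour_stream <- function(series,
                             behaviour = c("all", "toddler_handle",
                                           "parent_handle", "parent_talk")) {
  stopifnot(inherits(series, "dyad_series"))
  behaviour <- match.arg(behaviour)
  ev <- series$events
  if (behaviour != "all") {
    parts <- strsplit(behaviour, "_", fixed = TRUE)[[1L]]
    ev <- ev[ev$agent == parts[1L] & ev$act == parts[2L], , drop = FALSE]
  }
  toys <- series$toy_universe
  counts <- table(factor(ev$toy, levels = toys))
  counts <- stats::setNames(as.integer(counts), toys)
  total <- sum(counts)
  props <- if (total > 0L) counts / total else counts * 0
  first_seg <- rep(Inf, length(toys))
  names(first_seg) <- toys
  if (nrow(ev) > 0L) {
    fs <- tapply(ev$segment, factor(ev$toy, levels = toys), min)
    first_seg[!is.na(fs)] <- fs[!is.na(fs)]
  }
  structure(
    list(behaviour = behaviour, counts = counts, proportions = props,
         total = total, first_segment = first_seg,
         dyad_id = series$dyad_id),
    class = "behaviour_stream"
  )
}

#' @export
print.behaviour_stream <- function(x, ...) {
  cat("<behaviour_stream> ", x$behaviour, ": ", x$total, " events over ",
      sum(x$counts > 0L), " toys\n", sep = "")
  invisible(x)
}

#' Export a behaviour stream as JSON
#'
#' @param stream a [behaviour_stream].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
stream_to_json <- function(stream, path = NULL) {
  stopifnot(inherits(stream, "behaviour_stream"))
  obj <- list(dyad = stream$dyad_id, behaviour = stream$behaviour,
              total = stream$total, counts = as.list(stream$counts),
              proportions = as.list(stream$proportions))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Toys with at least one selection act
#'
#' @param series a [dyad_series].
#' @return Sorted character vector of the toys the dyad selected, the node
#'   set of the dyad's transition network.
#' @export
selected_toys <- function(series) sort(unique(series$events$toy))
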