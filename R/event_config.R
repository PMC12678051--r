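#' Define the event set of a z-score subtype-and-stage model
#'
#' An "event" is a (biomarker, abnormality level) pair: the moment a
#' biomarker's abnormality z-score crosses one of its configured
#' thresholds. With `B` biomarkers carrying `R_b` thresholds each, the
#' model has `N = sum(R_b)` events and stages `0..N`; the default of
#' three thresholds per biomarker on six biomarkers yields the 18-stage
#' construction used throughout.
#'
#' Two threshold conventions are in circulation for this model family:
#' mild/intermediate/severe at 1/2/3 reference standard deviations
#' (the default here, with ceiling `z_max = 5`), and a coarser 4/6/8
#' grid with ceiling 10 (available via [event_config_z468()]).
#' Thresholds are fully configurable per biomarker.
#'
#' @param biomarkers character vector of biomarker (column) names.
#' @param thresholds strictly increasing positive numeric vector of
#'   abnormality thresholds shared by all biomarkers, or a named list
#'   with one such vector per biomarker.
#' @param z_max trajectory ceiling, strictly greater than the largest
#'   threshold; scalar or named vector per biomarker.
#' @param sigma Gaussian noise standard deviation around the trajectory;
#'   scalar or named vector per biomarker. Inputs are z-scores, so the
#'   default is 1.
#' @return An object of class `event_config`: a list with `biomarkers`,
#'   `events` (data.frame with columns `biomarker`, `level`,
#'   `threshold`), `z_max`, `sigma` and `n_events`.
#' @examples
#' cfg <- event_config(c("dgm_volume", "snfl"))
#' cfg$n_events  # 6
#' @export
event_config <- function(biomarkers, thresholds = c(1, 2, 3),
                         z_max = 5, sigma = 1) {
  if (!is.character(biomarkers) || length(biomarkers) < 1L ||
      anyDuplicated(biomarkers))
    stop("'biomarkers' must be unique non-empty names", call. = FALSE)
  B <- length(biomarkers)
  if (!is.list(thresholds)) {
    thresholds <- stats::setNames(rep(list(as.numeric(thresholds)), B),
                                  biomarkers)
  }
  if (!setequal(names(thresholds), biomarkers))
    stop("threshold list must name every biomarker exactly once",
         call. = FALSE)
  thresholds <- thresholds[biomarkers]
  for (b in biomarkers) {
    th <- thresholds[[b]]
    if (length(th) < 1L || any(th <= 0) || is.unsorted(th, strictly = TRUE))
      stop("thresholds for '", b,
           "' must be strictly increasing and positive", call. = FALSE)
  }
  z_max <- .per_biomarker(z_max, biomarkers, "z_max")
  sigma <- .per_biomarker(sigma, biomarkers, "sigma")
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  for (b in biomarkers) {
    if (z_max[[b]] <= max(thresholds[[b]]))
      stop("z_max for '", b, "' must exceed its last threshold",
           call. = FALSE)
  }
  events <- do.call(rbind, lapply(biomarkers, function(b) {
    data.frame(biomarker = b,
               level = seq_along(thresholds[[b]]),
               threshold = thresholds[[b]],
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  structure(list(biomarkers = biomarkers,
                 thresholds = thresholds,
                 events = events,
                 z_max = z_max,
                 sigma = sigma,
                 n_events = nrow(events)),
            class = "event_config")
}

.per_biomarker <- function(x, biomarkers, what) {
  if (length(x) == 1L) x <- stats::setNames(rep(as.numeric(x),
                                                length(biomarkers)),
                                            biomarkers)
  if (is.null(names(x)) && length(x) == length(biomarkers))
    names(x) <- biomarkers
  if (!setequal(names(x), biomarkers))
    stop("'", what, "' must be a scalar or named per biomarker",
         call. = FALSE)
  x[biomarkers]
}

#' @rdname event_config
#' @export
event_config_z468 <- function(biomarkers) {
  event_config(biomarkers, thresholds = c(4, 6, 8), z_max = 10)
}

#' @export
print.event_config <- function(x, ...) {
  cat("Event configuration:", length(x$biomarkers), "biomarkers,",
      x$n_events, "events (stages 0 -", x$n_events, ")\n")
  for (b in x$biomarkers)
    cat("  ", b, ": thresholds ",
        paste(x$thresholds[[b]], collapse = " < "),
        ", ceiling ", x$z_max[[b]], ", sigma ", x$sigma[[b]], "\n",
        sep = "")
  invisible(x)
}

# --- event sequences -------------------------------------------------

#' Validate an event sequence against its configuration
#'
#' A sequence is a permutation of all events in which, for every
#' biomarker, level j precedes level j+1; position is the 1-based stage
#' at which the event occurs.
#'
#' @param sequence integer vector of event indices (rows of
#'   `config$events`) in stage order.
#' @param config an [event_config()].
#' @return `TRUE` invisibly, or an error.
#' @export
validate_sequence <- function(sequence, config) {
  N <- config$n_events
  if (length(sequence) != N || !setequal(sequence, seq_len(N)))
    stop("sequence must be a permutation of all ", N, " events",
         call. = FALSE)
  ev <- config$events
  pos <- order(sequence)  # pos[e] = position of event e
  for (b in config$biomarkers) {
    p <- pos[which(ev$biomarker == b)]
    if (is.unsorted(p, strictly = TRUE))
      stop("within-biomarker level order violated for '", b, "'",
           call. = FALSE)
  }
  invisible(TRUE)
}

# positions of each event: event_positions(seq)[e] = stage of event e
event_positions <- function(sequence) order(sequence)

# admissible insertion window (lo..hi, positions in the full-length
# sequence) for the event currently at position `from`
.admissible_window <- function(sequence, from, config) {
  e <- sequence[from]
  ev <- config$events
  b <- ev$biomarker[e]; lv <- ev$level[e]
  pos <- event_positions(sequence)
  same <- which(ev$biomarker == b)
  lo <- 1L; hi <- config$n_events
  prev <- same[ev$level[same] == lv - 1L]
  nxt <- same[ev$level[same] == lv + 1L]
  if (length(prev)) lo <- pos[prev] + 1L
  if (length(nxt)) hi <- pos[nxt] - 1L
  c(lo, hi)
}

# relocate the event at position `from` to position `to`
.relocate <- function(sequence, from, to) {
  e <- sequence[from]
  s <- sequence[-from]
  append(s, e, after = to - 1L)
}

#' Draw a random admissible event sequence
#'
#' Builds a sequence by repeatedly choosing uniformly among events whose
#' lower levels have all been placed (a random topological order of the
#' within-biomarker level constraints).
#'
#' @inheritParams validate_sequence
#' @return integer event-index vector of length `config$n_events`.
#' @export
random_sequence <- function(config) {
  ev <- config$events
  N <- config$n_events
  placed <- logical(N)
  out <- integer(N)
  for (p in seq_len(N)) {
    ready <- which(!placed & (ev$level == 1L | vapply(seq_len(N),
      function(e) {
        if (placed[e] || ev$level[e] == 1L) return(FALSE)
        prev <- which(ev$biomarker == ev$biomarker[e] &
                        ev$level == ev$level[e] - 1L)
        placed[prev]
      }, logical(1))))
    pick <- if (length(ready) == 1L) ready else sample(ready, 1L)
    out[p] <- pick
    placed[pick] <- TRUE
  }
  out
}

# all admissible sequences (linear extensions); only for tiny N
enumerate_sequences <- function(config) {
  ev <- config$events
  N <- config$n_events
  res <- list()
  recurse <- function(prefix, placed) {
    if (length(prefix) == N) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (e in seq_len(N)) {
      if (placed[e]) next
      if (ev$level[e] > 1L) {
        prev <- which(ev$biomarker == ev$biomarker[e] &
                        ev$level == ev$level[e] - 1L)
        if (!placed[prev]) next
      }
      placed[e] <- TRUE
      recurse(c(prefix, e), placed)
      placed[e] <- FALSE
    }
  }
  recurse(integer(0), logical(N))
  res
}

# human-readable event labels, e.g. "dgm_volume:2"
event_labels <- function(config)
  paste(config$events$biomarker, config$events$level, sep = ":")
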