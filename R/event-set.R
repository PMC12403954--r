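#' Define the event grid of a z-score progression model
#'
#' An event is a biomarker crossing a fixed atrophy z-threshold. The event
#' set holds, for each biomarker, its ordered thresholds (by default z = 1,
#' 2, 3), the ceiling value `z_max` the trajectory reaches at the final
#' stage, and the Gaussian observation SD `sigma` used in the likelihood.
#' The total number of events `E` is the sum of threshold counts, and model
#' stages run 0 (no events) to `E` (all events occurred).
#'
#' @param biomarkers character vector of biomarker names.
#' @param z_levels numeric vector of thresholds shared by all biomarkers, or
#'   a named list giving per-biomarker thresholds. Must be strictly
#'   increasing and positive.
#' @param z_max ceiling z reached at stage `E`; scalar or per-biomarker
#'   vector. Must exceed each biomarker's largest threshold.
#' @param sigma observation SD per biomarker (default 1: data are
#'   HC-referenced z-scores).
#' @return An object of class `event_set` with components `biomarkers`,
#'   `events` (data.frame with columns `biomarker`, `level` in canonical
#'   biomarker-major order), `E`, `z_max`, `sigma`.
#' @examples
#' es <- event_set(c("cortical_gm", "mucca"))
#' es$E  # 6 events: two biomarkers x thresholds 1,2,3
#' @export
event_set <- function(biomarkers, z_levels = c(1, 2, 3), z_max = 5, sigma = 1) {
  biomarkers <- as.character(biomarkers)
  if (anyDuplicated(biomarkers)) stop_input("duplicate biomarker names")
  B <- length(biomarkers)
  if (B < 1L) stop_input("need at least one biomarker")
  if (!is.list(z_levels)) z_levels <- rep(list(as.numeric(z_levels)), B)
  if (length(z_levels) != B) stop_input("z_levels must match biomarker count")
  names(z_levels) <- biomarkers
  for (b in biomarkers) {
    zl <- z_levels[[b]]
    if (length(zl) < 1L || any(!is.finite(zl)) || any(diff(zl) <= 0))
      stop_input("thresholds for '%s' must be finite and strictly increasing", b)
  }
  z_max <- rep_len(as.numeric(z_max), B)
  names(z_max) <- biomarkers
  for (b in biomarkers) {
    if (z_max[[b]] <= max(z_levels[[b]]))
      stop_input("z_max for '%s' must exceed its largest threshold", b)
  }
  sigma <- rep_len(as.numeric(sigma), B)
  if (any(sigma <= 0)) stop_input("sigma must be positive")
  names(sigma) <- biomarkers
  events <- data.frame(
    biomarker = rep(biomarkers, lengths(z_levels)),
    level = unlist(z_levels, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  ## cached index structures used by the fitting hot paths
  ev_b <- match(events$biomarker, biomarkers)
  byb <- unname(split(seq_len(nrow(events)), ev_b))
  prev_ev <- next_ev <- integer(nrow(events))
  for (idx in byb) {
    if (length(idx) > 1L) {
      prev_ev[idx[-1L]] <- idx[-length(idx)]
      next_ev[idx[-length(idx)]] <- idx[-1L]
    }
  }
  structure(
    list(biomarkers = biomarkers, z_levels = z_levels, events = events,
         E = nrow(events), z_max = z_max, sigma = sigma,
         ev_biomarker = ev_b, byb = byb, prev_ev = prev_ev, next_ev = next_ev,
         has_next = which(next_ev > 0L)),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("Event set: %d biomarkers, %d events (stages 0..%d)\n",
              length(x$biomarkers), x$E, x$E))
  for (b in x$biomarkers) {
    cat(sprintf("  %-20s thresholds %s, z_max %g, sigma %g\n", b,
                paste(x$z_levels[[b]], collapse = "/"),
                x$z_max[[b]], x$sigma[[b]]))
  }
  invisible(x)
}

## event indices (rows of es$events) belonging to each biomarker, in
## increasing-threshold order
events_by_biomarker <- function(es) es$byb

## positions vector: pos[e] = stage position of event e
ordering_positions <- function(es, ordering) {
  pos <- integer(es$E)
  pos[ordering] <- seq_len(es$E)
  pos
}

## constraint check only (assumes `ordering` is a permutation of 1..E)
valid_positions_fast <- function(es, ordering) {
  pos <- ordering_positions(es, ordering)
  hn <- es$has_next
  all(pos[hn] < pos[es$next_ev[hn]])
}

#' Validate an event ordering
#'
#' An ordering is a permutation of the event indices `1..E` (rows of
#' `es$events`) giving each event's stage position; within each biomarker,
#' thresholds must be crossed in increasing order.
#'
#' @param es an [event_set()].
#' @param ordering integer vector of length `E`; `ordering[p]` is the event
#'   occupying stage position `p`.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_ordering <- function(es, ordering) {
  if (length(ordering) != es$E || anyDuplicated(ordering) ||
      !all(sort(ordering) == seq_len(es$E))) return(FALSE)
  valid_positions_fast(es, ordering)
}

assert_ordering <- function(es, ordering) {
  if (!is_valid_ordering(es, ordering))
    stop_input("invalid ordering: not a permutation of the event grid respecting within-biomarker threshold order")
  invisible(ordering)
}

#' Draw a uniformly random valid ordering
#'
#' Shuffles biomarker slots and fills each biomarker's events in threshold
#' order, which samples uniformly from the constrained permutation space.
#'
#' @inheritParams is_valid_ordering
#' @param seed optional RNG seed.
#' @return an integer ordering vector.
#' @export
random_ordering <- function(es, seed = NULL) {
  maybe_seed(seed)
  byb <- events_by_biomarker(es)
  labels <- rep(seq_along(byb), lengths(byb))
  slots <- sample(labels)
  out <- integer(es$E)
  used <- integer(length(byb))
  for (p in seq_len(es$E)) {
    b <- slots[p]
    used[b] <- used[b] + 1L
    out[p] <- byb[[b]][used[b]]
  }
  out
}

#' Enumerate all valid orderings of a small event set
#'
#' Exhaustively lists the constrained permutations (all interleavings that
#' keep each biomarker's thresholds in increasing order). Intended for
#' exact-posterior cross-checks on event sets with small `E`.
#'
#' @inheritParams is_valid_ordering
#' @param max_E guard against combinatorial blow-up (default 8).
#' @return list of ordering vectors.
#' @export
enumerate_orderings <- function(es, max_E = 8L) {
  if (es$E > max_E) stop_input("E = %d too large to enumerate (max_E = %d)", es$E, max_E)
  byb <- events_by_biomarker(es)
  counts0 <- lengths(byb)
  res <- list()
  recurse <- function(prefix, used) {
    if (length(prefix) == es$E) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_along(byb)) {
      if (used[b] < counts0[b]) {
        used2 <- used
        used2[b] <- used[b] + 1L
        recurse(c(prefix, byb[[b]][used2[b]]), used2)
      }
    }
  }
  recurse(integer(0), integer(length(byb)))
  res
}

#' Piecewise-linear z-score trajectory of one biomarker
#'
#' Expected z of biomarker `b` at (possibly fractional) stage `k`, under an
#' ordering: linear interpolation through the anchors `(0, 0)`, each of the
#' biomarker's `(event position, threshold)` pairs, and `(E, z_max_b)`. The
#' trajectory is nondecreasing and reaches `z_max_b` exactly at `k = E` (the
#' ceiling anchor takes precedence if the last threshold sits at position
#' `E`).
#'
#' @inheritParams is_valid_ordering
#' @param biomarker biomarker name.
#' @param k numeric vector of stages in `[0, E]`.
#' @return numeric vector of expected z-scores.
#' @export
trajectory <- function(es, ordering, biomarker, k) {
  assert_ordering(es, ordering)
  if (!biomarker %in% es$biomarkers) stop_input("unknown biomarker '%s'", biomarker)
  if (any(!is.finite(k)) || any(k < 0 | k > es$E))
    stop_input("stage k must lie in [0, %d]", es$E)
  pos <- order(ordering)
  idx <- which(es$events$biomarker == biomarker)
  x <- c(0, pos[idx], es$E)
  y <- c(0, es$events$level[idx], es$z_max[[biomarker]])
  if (x[length(x) - 1L] == es$E) { # last threshold at E: ceiling wins there
    x <- x[-(length(x) - 1L)]
    y <- y[-(length(y) - 1L)]
  }
  stats::approx(x, y, xout = k, method = "linear", ties = "ordered")$y
}

## (E+1) x B matrix of trajectory values at integer stages 0..E.
## No validity check: fitting hot path (candidates are valid by construction).
traj_matrix_fast <- function(es, ordering) {
  E <- es$E
  pos <- ordering_positions(es, ordering)
  k <- 0:E
  B <- length(es$biomarkers)
  G <- matrix(0, E + 1L, B)
  for (b in seq_len(B)) {
    idx <- es$byb[[b]]
    xs <- c(0, pos[idx], E)
    ys <- c(0, es$events$level[idx], es$z_max[[b]])
    nn <- length(xs)
    if (xs[nn - 1L] == E) { # ceiling anchor wins at k = E
      xs <- xs[-(nn - 1L)]
      ys <- ys[-(nn - 1L)]
    }
    j <- findInterval(k, xs, rightmost.closed = TRUE)
    G[, b] <- ys[j] + (k - xs[j]) * (ys[j + 1L] - ys[j]) / (xs[j + 1L] - xs[j])
  }
  colnames(G) <- es$biomarkers
  G
}

## validated variant for entry points
traj_matrix <- function(es, ordering) {
  assert_ordering(es, ordering)
  traj_matrix_fast(es, ordering)
}

#' Serialize / restore an event set and orderings as JSON
#'
#' @param es an [event_set()].
#' @param orderings optional list of ordering vectors to store alongside.
#' @param path file path.
#' @return `write_event_set_json` returns `path` invisibly;
#'   `read_event_set_json` returns a list with `event_set` and `orderings`.
#' @export
write_event_set_json <- function(es, path, orderings = NULL) {
  obj <- list(
    biomarkers = es$biomarkers,
    z_levels = es$z_levels,
    z_max = as.list(es$z_max),
    sigma = as.list(es$sigma),
    orderings = orderings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_event_set_json
#' @export
read_event_set_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  es <- event_set(obj$biomarkers,
                  z_levels = as.list(obj$z_levels)[obj$biomarkers],
                  z_max = unlist(obj$z_max)[obj$biomarkers],
                  sigma = unlist(obj$sigma)[obj$biomarkers])
  ords <- obj$orderings
  if (!is.null(ords)) {
    if (is.matrix(ords)) ords <- lapply(seq_len(nrow(ords)), function(i) as.integer(ords[i, ]))
    else ords <- lapply(ords, as.integer)
  }
  list(event_set = es, orderings = ords)
}
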