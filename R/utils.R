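#' Canonical brain-state labels, ordered deepest to awake
#'
#' The six-level state factor used throughout the package: five isoflurane
#' concentrations plus the awake state, ordered from deepest anesthesia to
#' wakefulness.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' wf_states()
wf_states <- function() {
  c("iso2.0", "iso1.75", "iso1.5", "iso1.0", "iso0.5", "awake")
}

#' Coerce to the ordered state factor
#'
#' @param x character vector of state labels.
#' @return Ordered factor with levels `wf_states()`, deepest first.
#' @export
state_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), wf_states())
  if (length(bad) > 0) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  }
  factor(as.character(x), levels = wf_states(), ordered = TRUE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# segments bookkeeping -------------------------------------------------------

#' Build a state segment table
#'
#' A segment table records which frames belong to which brain state:
#' columns `state`, `start`, `end` with 1-based inclusive frame ranges,
#' disjoint and ordered deepest state first.
#'
#' @param states character vector of state labels, one per segment.
#' @param lengths integer vector of segment lengths (frames).
#' @return data.frame with columns `state`, `start`, `end`.
#' @export
make_segments <- function(states, lengths) {
  end <- cumsum(lengths)
  start <- end - lengths + 1L
  data.frame(state = as.character(states), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

check_segments <- function(segments, n_frames) {
  stopifnot(is.data.frame(segments),
            all(c("state", "start", "end") %in% names(segments)))
  if (any(segments$start > segments$end)) stop("segment with start > end")
  if (any(segments$start < 1L) || any(segments$end > n_frames)) {
    stop("segments outside [1, T]")
  }
  if (nrow(segments) > 1) {
    if (any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      stop("segments overlap or are unordered")
    }
  }
  invisible(segments)
}

#' Frame indices of one state in a segment table
#'
#' @param segments a segment table (see [make_segments()]).
#' @param state state label.
#' @return Integer vector of frame indices (empty if the state is absent).
#' @export
segment_frames <- function(segments, state) {
  i <- which(segments$state == state)
  if (length(i) == 0) return(integer(0))
  unlist(lapply(i, function(j) seq.int(segments$start[j], segments$end[j])),
         use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
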