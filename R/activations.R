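#' Activation thresholds from the deepest-anesthesia reference
#'
#' Computes the positive and negative activation thresholds of an IC time
#' course as the mean of its deepest-state (iso 2%) segment plus/minus
#' `k_sigma` standard deviations of that segment — the global-inactivation
#' reference against which significant activations are defined.
#'
#' @param tc numeric time course over the whole concatenated session.
#' @param segments the session's state segment table.
#' @param ref_state reference state label (default `"iso2.0"`).
#' @param k_sigma threshold multiplier (default 3).
#' @return Named vector `c(th_pos, th_neg)`.
#' @export
compute_thresholds <- function(tc, segments, ref_state = "iso2.0",
                               k_sigma = 3) {
  fr <- segment_frames(segments, ref_state)
  if (length(fr) == 0) stop("reference state ", ref_state, " has no frames")
  mu <- mean(tc[fr]); s <- stats::sd(tc[fr])
  if (!is.finite(s) || s == 0) {
    stop("degenerate reference: sd of the ", ref_state, " segment is 0")
  }
  c(th_pos = mu + k_sigma * s, th_neg = mu - k_sigma * s)
}

#' Binarize a time course against activation thresholds
#'
#' `1` whenever the time course strictly exceeds the positive threshold or
#' strictly undercuts the negative one, `0` otherwise (values exactly at a
#' threshold are 0).
#'
#' @param tc numeric time course.
#' @param th_pos,th_neg thresholds with `th_pos > th_neg`.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(tc, th_pos, th_neg) {
  if (!(th_pos > th_neg)) stop("th_pos must exceed th_neg")
  as.integer(tc > th_pos | tc < th_neg)
}

#' Activation counts and relative occurrence per state
#'
#' For each state ST and IC, the number of activations `N[IC, ST]` is the
#' count of suprathreshold frames (the sum of the binary vector within the
#' state segment), and the relative occurrence `N[IC, ST] / sum_IC N[IC, ST]`
#' is the proportion of significant timepoints attributed to that IC in that
#' state. States with no crossings at all yield `NA` proportions (0/0 is
#' reported as missing, not zero).
#'
#' @param binaries `T x K` matrix of 0/1 activation vectors (retained ICs).
#' @param segments the session's state segment table.
#' @return List with `counts` and `rel_occurrence` (states x K matrices).
#' @export
count_and_proportion <- function(binaries, segments) {
  stopifnot(is.matrix(binaries), ncol(binaries) >= 1)
  states <- segments$state
  counts <- t(vapply(states, function(st) {
    colSums(binaries[segment_frames(segments, st), , drop = FALSE])
  }, numeric(ncol(binaries))))
  rownames(counts) <- states
  tot <- rowSums(counts)
  rel <- counts / tot
  rel[tot == 0, ] <- NA_real_
  list(counts = counts, rel_occurrence = rel)
}

#' Bootstrap expected-occurrence null
#'
#' Builds the state-free expected proportion of activations per IC by
#' pooling the IC identities of all threshold crossings in the deepest
#' anesthesia state and in the awake state, then drawing `n_per_state`
#' crossings with replacement from each pool (`n_sim = 2 * n_per_state`
#' draws in total). The expected proportion of an IC is its share of the
#' simulated crossings — a reference distribution free from bias due to
#' differences in crossing numbers between states.
#'
#' @param binaries `T x K` binary activation matrix.
#' @param segments state segment table.
#' @param n_sim total simulated crossings (must equal `2 * n_per_state`).
#' @param n_per_state draws per reference state.
#' @param seed integer seed; the draw is reproducible given it.
#' @param ref_states the two reference states (deepest, awake).
#' @return An object of class `wf_null`: `expected` (length-K proportions
#'   summing to 1), `pools` (crossing counts per IC per reference state),
#'   `n_sim`, `n_per_state`, `seed`.
#' @export
expected_null <- function(binaries, segments, n_sim = 10000L,
                          n_per_state = 5000L, seed = 1L,
                          ref_states = c("iso2.0", "awake")) {
  if (n_sim != 2L * n_per_state) {
    stop("n_sim must equal 2 * n_per_state (one half per reference state)")
  }
  K <- ncol(binaries)
  pools <- lapply(ref_states, function(st) {
    fr <- segment_frames(segments, st)
    ids <- rep(seq_len(K), colSums(binaries[fr, , drop = FALSE]))
    if (length(ids) == 0) stop("no threshold crossings in state ", st)
    ids
  })
  draws <- with_seed(seed, unlist(lapply(pools, function(p) {
    p[sample.int(length(p), n_per_state, replace = TRUE)]
  })))
  expected <- tabulate(draws, nbins = K) / n_sim
  structure(list(expected = expected,
                 pools = vapply(pools, tabulate, nbins = K,
                                FUN.VALUE = numeric(K)),
                 n_sim = n_sim, n_per_state = n_per_state, seed = seed,
                 ref_states = ref_states),
            class = "wf_null")
}

#' @export
print.wf_null <- function(x, ...) {
  cat("Expected-occurrence null (", x$n_sim, "draws,", x$n_per_state,
      "per state from", paste(x$ref_states, collapse = " + "), ")\n")
  print(round(x$expected, 4))
  invisible(x)
}

#' Prominent components of a brain state
#'
#' A component is prominent in a state when the lower bound of the t-based
#' 95% confidence interval of its relative occurrence across subjects
#' exceeds its bootstrap-expected proportion.
#'
#' @param occurrence `subjects x K` matrix of per-subject relative
#'   occurrence in the state (>= 2 subjects).
#' @param null a `wf_null` (or a plain vector of expected proportions).
#' @param conf confidence level (default 0.95).
#' @return Data frame with `ic_id`, `mean`, `ci_lower`, `ci_upper`,
#'   `expected`, `prominent`.
#' @export
prominent_components <- function(occurrence, null, conf = 0.95) {
  stopifnot(is.matrix(occurrence))
  n <- nrow(occurrence)
  if (n < 2) stop("confidence interval undefined with fewer than 2 subjects")
  expected <- if (inherits(null, "wf_null")) null$expected else null
  stopifnot(length(expected) == ncol(occurrence))
  m <- colMeans(occurrence)
  se <- apply(occurrence, 2, stats::sd) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  data.frame(ic_id = seq_along(m), mean = m,
             ci_lower = m - tq * se, ci_upper = m + tq * se,
             expected = expected,
             prominent = m - tq * se > expected)
}

#' Aggregate relative occurrence by macro group
#'
#' Averages relative occurrence over the retained ICs of each macro group,
#' then over the sessions of each subject, and summarizes across subjects
#' with a t-based 95% confidence interval. Groups with no retained ICs (or
#' states with no crossings) are reported as missing.
#'
#' @param labels a `wf_labels` annotation table.
#' @param records list with one element per session: `rel_occurrence`
#'   (states x K matrix from [count_and_proportion()]) and `subject_id`.
#' @param conf confidence level for the group summary.
#' @return List (class `wf_occurrence`): `per_subject` (long data frame:
#'   subject, state, group, value) and `summary` (state, group, mean,
#'   ci_lower, ci_upper, n_subjects).
#' @export
occurrence_by_group <- function(labels, records, conf = 0.95) {
  keep <- labels$ic_id[labels$retained]
  if (length(keep) == 0) stop("no retained ICs")
  groups <- sort(unique(labels$group[labels$retained]))
  rows <- list()
  for (rec in records) {
    rel <- rec$rel_occurrence
    for (st in rownames(rel)) {
      for (g in groups) {
        ics <- labels$ic_id[labels$retained & labels$group == g]
        rows[[length(rows) + 1]] <- data.frame(
          subject = rec$subject_id, state = st, group = g,
          value = mean(rel[st, ics]), stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  per_subject <- stats::aggregate(value ~ subject + state + group, long,
                                  mean, na.action = stats::na.pass)
  agg <- stats::aggregate(value ~ state + group, per_subject, function(v) {
    v <- v[is.finite(v)]
    n <- length(v)
    if (n == 0) return(c(mean = NA_real_, lo = NA_real_, up = NA_real_,
                         n = 0))
    m <- mean(v)
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) *
      stats::sd(v) / sqrt(n) else NA_real_
    c(mean = m, lo = m - half, up = m + half, n = n)
  }, na.action = stats::na.pass)
  summary <- data.frame(state = agg$state, group = agg$group,
                        mean = agg$value[, "mean"],
                        ci_lower = agg$value[, "lo"],
                        ci_upper = agg$value[, "up"],
                        n_subjects = agg$value[, "n"])
  structure(list(per_subject = per_subject, summary = summary),
            class = "wf_occurrence")
}

#' @export
print.wf_occurrence <- function(x, ...) {
  cat("Relative occurrence by macro group (subject means):\n")
  wide <- stats::reshape(x$summary[, c("state", "group", "mean")],
                         idvar = "group", timevar = "state",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(format(wide, digits = 3), row.names = FALSE)
  invisible(x)
}
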