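#' Phi correlation between two binary activation vectors
#'
#' Pearson correlation of two 0/1 vectors (the phi coefficient): 1 when the
#' ICs are always co-activated, -1 when they activate in strictly different
#' timepoints. Requires each vector to contain at least one 0 and one 1; a
#' constant vector yields `NA` with a warning.
#'
#' @param binary_i,binary_j 0/1 vectors of equal length.
#' @return Correlation coefficient, or `NA` for a degenerate input.
#' @export
binary_corr <- function(binary_i, binary_j) {
  stopifnot(length(binary_i) == length(binary_j))
  if (stats::var(binary_i) == 0 || stats::var(binary_j) == 0) {
    warning("constant binary vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(binary_i, binary_j)
}

#' Per-state co-occurrence matrices
#'
#' For every brain state, the `K x K` matrix of Pearson correlations between
#' the ICs' binary activation vectors restricted to that state's frames.
#' Matrices are symmetric with unit diagonal; entries involving a vector
#' that is constant within the state are `NA`.
#'
#' @param binaries `T x K` binary activation matrix for one session.
#' @param segments state segment table.
#' @return Named list of `K x K` matrices, one per state.
#' @export
state_matrices <- function(binaries, segments) {
  K <- ncol(binaries)
  out <- lapply(segments$state, function(st) {
    B <- binaries[segment_frames(segments, st), , drop = FALSE]
    sds <- apply(B, 2, stats::sd)
    R <- suppressWarnings(stats::cor(B))
    R[sds == 0, ] <- NA_real_
    R[, sds == 0] <- NA_real_
    diag(R) <- 1
    R
  })
  names(out) <- segments$state
  out
}

#' Fisher-z mean of within-group correlations
#'
#' Transforms every within-group pair correlation with the Fisher z
#' (`atanh`), clipping `|r|` at `1 - 1e-6` so exactly coincident binary
#' vectors stay finite, and averages. Groups with fewer than two retained
#' ICs yield `NA`.
#'
#' @param mat `K x K` correlation matrix.
#' @param labels a `wf_labels` table.
#' @param group macro-group name.
#' @return Named vector `c(z, r)`: the mean Fisher z and its back-transform
#'   `tanh(z)`.
#' @export
fisher_group_mean <- function(mat, labels, group) {
  ics <- labels$ic_id[labels$retained & labels$group == group]
  if (length(ics) < 2) return(c(z = NA_real_, r = NA_real_))
  sub <- mat[ics, ics, drop = FALSE]
  rs <- sub[upper.tri(sub)]
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) return(c(z = NA_real_, r = NA_real_))
  z <- mean(atanh(pmin(pmax(rs, -1 + 1e-6), 1 - 1e-6)))
  c(z = z, r = tanh(z))
}

#' Subject-level co-occurrence summary by macro group
#'
#' Computes per-session, per-state co-occurrence matrices, takes the Fisher-z
#' mean over within-group IC pairs, and averages over each subject's
#' sessions, producing the subject x state x group table used for the
#' repeated-measures analysis.
#'
#' @param labels a `wf_labels` table.
#' @param records list per session with `binaries` (`T x K_retained`),
#'   `segments`, `subject_id`, and optionally `ic_ids` giving the original
#'   IC id of each binary column (defaults to `1..K`).
#' @param group macro-group name (default `"Retrosplenial"`).
#' @return Data frame with columns `subject`, `state`, `z`, `r`.
#' @export
cooccurrence_by_group <- function(labels, records, group = "Retrosplenial") {
  rows <- lapply(records, function(rec) {
    # remap label ids onto the binary-matrix columns
    labs <- labels
    labs$ic_id <- match(labels$ic_id,
                        rec$ic_ids %||% seq_len(ncol(rec$binaries)))
    labs <- labs[!is.na(labs$ic_id), , drop = FALSE]
    mats <- state_matrices(rec$binaries, rec$segments)
    do.call(rbind, lapply(names(mats), function(st) {
      zr <- fisher_group_mean(mats[[st]], labs, group)
      data.frame(subject = rec$subject_id, state = st, z = zr["z"],
                 r = zr["r"], stringsAsFactors = FALSE)
    }))
  })
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(z, r) ~ subject + state, long, mean,
                          na.action = stats::na.pass)
  agg[order(agg$subject, state_factor(agg$state)), ]
}
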