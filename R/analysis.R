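#' Run the full analysis chain on a synthetic study
#'
#' Orchestrates, in memory: session rendering, preprocessing (dF/F0 +
#' zero-phase high-pass over the atlas mask), group ICA with ICASSO,
#' atlas annotation with artifact flagging, threshold-based activation
#' statistics with the bootstrap expected-occurrence null, co-occurrence
#' matrices, and the repeated-measures state tests. Sessions are rendered
#' one at a time so only one raw movie is ever held in memory.
#'
#' @param study a `wf_study` from [simulate_study()].
#' @param k number of group components (defaults to the number of designed
#'   sources).
#' @param n_runs ICASSO runs.
#' @param mode ICASSO resampling mode.
#' @param seed seed for the ICA stage.
#' @param cutoff high-pass cutoff, Hz.
#' @param k_sigma activation-threshold multiplier.
#' @param n_per_state bootstrap draws per reference state.
#' @param null_seed seed for the bootstrap null.
#' @param midline_frac,elongation artifact-flagging thresholds.
#' @param keep_dff keep the preprocessed sessions in the result (memory!).
#' @return An object of class `wf_analysis`; see Details.
#' @details The result bundles `fit` (the [wfica()] object), `labels`
#'   (annotation table), `records` (per session: binary activation matrix of
#'   retained ICs, counts, relative occurrence), `occurrence`
#'   (group-averaged table), `null` (bootstrap expected proportions, pooled
#'   over sessions), `prominent` (per state), `cooccurrence` (per-state
#'   subject summary for every macro group), `global_phi` (mean off-diagonal
#'   co-occurrence per state), and the ANOVA/post hoc tables for the
#'   retrosplenial group (`anova_occurrence`, `anova_cooccurrence`,
#'   `posthoc_occurrence`, `posthoc_cooccurrence`).
#' @export
analyze_study <- function(study, k = study$design$n_sources, n_runs = 10L,
                          mode = "both", seed = 1L, cutoff = 0.1,
                          k_sigma = 3, n_per_state = 5000L, null_seed = 1L,
                          midline_frac = 0.5, elongation = 4,
                          keep_dff = FALSE) {
  mask <- common_mask(lapply(seq_len(study$n_sessions),
                             function(i) study$atlas$mask))
  dff <- lapply(seq_len(study$n_sessions), function(i) {
    preprocess_session(study_session(study, i), mask, cutoff = cutoff)
  })
  fit <- wfica(dff, k = k, n_runs = n_runs, mode = mode, seed = seed)
  if (!keep_dff) dff <- NULL
  labels <- flag_artifacts(fit$maps, study$atlas, mask,
                           midline_frac = midline_frac,
                           elongation = elongation)
  res <- activation_statistics(fit, labels, k_sigma = k_sigma,
                               n_per_state = n_per_state,
                               null_seed = null_seed)
  structure(c(list(fit = fit, labels = labels, study = study, dff = dff),
              res), class = "wf_analysis")
}

# activation, occurrence, null, co-occurrence and state tests, given a fit
# and an annotation table
activation_statistics <- function(fit, labels, k_sigma = 3,
                                  n_per_state = 5000L, null_seed = 1L) {
  keep <- labels$ic_id[labels$retained]
  records <- lapply(fit$sessions, function(ses) {
    tcs <- ses$timecourses
    bin <- vapply(keep, function(i) {
      th <- compute_thresholds(tcs[i, ], ses$segments, k_sigma = k_sigma)
      binarize(tcs[i, ], th["th_pos"], th["th_neg"])
    }, integer(ncol(tcs)))
    cp <- count_and_proportion(bin, ses$segments)
    rel <- matrix(NA_real_, nrow(cp$rel_occurrence), nrow(labels),
                  dimnames = list(rownames(cp$rel_occurrence), NULL))
    rel[, keep] <- cp$rel_occurrence
    counts <- matrix(0, nrow(cp$counts), nrow(labels),
                     dimnames = list(rownames(cp$counts), NULL))
    counts[, keep] <- cp$counts
    list(binaries = bin, ic_ids = keep, counts = counts,
         rel_occurrence = rel, segments = ses$segments,
         subject_id = ses$subject_id, session_id = ses$session_id)
  })

  occurrence <- occurrence_by_group(labels, records)

  # pooled bootstrap null across sessions: stack binary matrices in time
  allbin <- do.call(rbind, lapply(records, `[[`, "binaries"))
  offs <- cumsum(c(0, vapply(records, function(r) max(r$segments$end),
                             numeric(1))))
  allseg <- do.call(rbind, lapply(seq_along(records), function(i) {
    s <- records[[i]]$segments
    s$start <- s$start + offs[i]; s$end <- s$end + offs[i]
    s
  }))
  null <- expected_null(allbin, allseg, n_sim = 2L * n_per_state,
                        n_per_state = n_per_state, seed = null_seed)

  # prominence per state: subject x retained-IC occurrence
  states <- records[[1]]$segments$state
  subjects <- unique(vapply(records, `[[`, "", "subject_id"))
  prominent <- lapply(states, function(st) {
    occ <- t(vapply(subjects, function(sb) {
      rows <- vapply(records, function(r) r$subject_id == sb, logical(1))
      colMeans(do.call(rbind, lapply(records[rows], function(r) {
        r$rel_occurrence[st, r$ic_ids]
      })), na.rm = TRUE)
    }, numeric(length(keep))))
    pc <- prominent_components(occ, null$expected)
    pc$ic_id <- keep
    pc
  })
  names(prominent) <- states

  groups <- unique(labels$group[labels$retained])
  cooc <- lapply(groups, function(g) cooccurrence_by_group(labels, records, g))
  names(cooc) <- groups

  global_phi <- vapply(states, function(st) {
    mean(vapply(records, function(r) {
      R <- state_matrices(r$binaries, r$segments)[[st]]
      mean(abs(R[upper.tri(R)]), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))

  occ_rsp <- occurrence_table(occurrence, "Retrosplenial")
  cooc_rsp <- cooc[["Retrosplenial"]]
  an_occ <- if (!is.null(occ_rsp)) try_anova(occ_rsp) else NULL
  an_cooc <- if (!is.null(cooc_rsp)) {
    tab <- data.frame(subject = cooc_rsp$subject, state = cooc_rsp$state,
                      value = cooc_rsp$z)
    try_anova(tab)
  } else NULL

  list(records = records, occurrence = occurrence, null = null,
       prominent = prominent, cooccurrence = cooc, global_phi = global_phi,
       anova_occurrence = an_occ,
       posthoc_occurrence = if (!is.null(occ_rsp)) posthoc_holm(occ_rsp),
       anova_cooccurrence = an_cooc,
       posthoc_cooccurrence = if (!is.null(cooc_rsp)) {
         posthoc_holm(data.frame(subject = cooc_rsp$subject,
                                 state = cooc_rsp$state,
                                 value = cooc_rsp$z))
       })
}

try_anova <- function(tab) {
  tryCatch(suppressMessages(rm_anova(tab)), error = function(e) NULL)
}

# subject x state long table of one group's occurrence
occurrence_table <- function(occurrence, group) {
  d <- occurrence$per_subject
  d <- d[d$group == group, c("subject", "state", "value")]
  if (nrow(d) == 0) return(NULL)
  d
}

#' @export
print.wf_analysis <- function(x, ...) {
  cat("Wide-field group ICA analysis\n")
  print(x$fit)
  cat("retained:", sum(x$labels$retained), "of", nrow(x$labels),
      "components\n")
  if (!is.null(x$anova_occurrence)) {
    cat("Retrosplenial occurrence: "); print(x$anova_occurrence)
  }
  if (!is.null(x$anova_cooccurrence)) {
    cat("Retrosplenial co-occurrence (Fisher z): ")
    print(x$anova_cooccurrence)
  }
  invisible(x)
}

# ---- evaluation against ground truth ---------------------------------------

#' Match fitted components to the ground-truth sources
#'
#' Rectangular assignment between the fitted group maps and the generator's
#' true source maps (restricted to the analysis mask).
#'
#' @param fit a `wfica` fit.
#' @param study the `wf_study` the data came from.
#' @return List with `match` (a `wf_match`), `mean_abs_r` over the true
#'   sources, and `source_ic` (fitted IC index per true source).
#' @export
evaluate_recovery <- function(fit, study) {
  truth_maps <- study$truths[[1]]$maps[, fit$pixel_idx, drop = FALSE]
  m <- match_components(truth_maps, fit$maps)
  list(match = m, mean_abs_r = mean(abs(m$r), na.rm = TRUE),
       source_ic = m$assignment)
}

#' Compare back-reconstructed and single-session components
#'
#' For every session, runs single-session ICASSO ICA at the fit's order on
#' the stored first-stage reduction, matches the session's
#' back-reconstructed group components to them by rectangular assignment,
#' and collects the matched absolute correlations.
#'
#' @param fit a `wfica` fit.
#' @param n_runs ICASSO runs for the single-session decompositions.
#' @param seed integer seed.
#' @return List with `r` (matched `|r|`, sessions x k), `median_r`.
#' @export
session_consistency <- function(fit, n_runs = 5L, seed = 1L) {
  k <- fit$k
  rs <- vapply(seq_along(fit$sessions), function(s) {
    X <- fit$reduction$sessions[[s]]$X
    ss <- icasso(X[seq_len(min(k, nrow(X))), , drop = FALSE],
                 min(k, nrow(X)), n_runs = n_runs, seed = seed + s)
    m <- match_components(fit$sessions[[s]]$maps, ss$maps)
    abs(m$r)
  }, numeric(k))
  list(r = t(rs), median_r = stats::median(rs, na.rm = TRUE))
}

#' Recovered phi of the designed retrosplenial pair, per state
#'
#' Maps the designed source pair onto fitted ICs via ground-truth matching
#' and returns the mean (over sessions) phi correlation between the two ICs'
#' binary activation vectors in every state.
#'
#' @param analysis a `wf_analysis`.
#' @return Named numeric vector, one value per state (`NA` when a pair
#'   member was not recovered or not retained).
#' @export
pair_phi <- function(analysis) {
  study <- analysis$study
  rec <- evaluate_recovery(analysis$fit, study)
  pr <- study$design$pairs[[1]]
  ics <- rec$source_ic[pr]
  states <- analysis$records[[1]]$segments$state
  out <- rep(NA_real_, length(states)); names(out) <- states
  if (any(is.na(ics))) return(out)
  for (st in states) {
    vals <- vapply(analysis$records, function(r) {
      ci <- match(ics, r$ic_ids)
      if (any(is.na(ci))) return(NA_real_)
      fr <- segment_frames(r$segments, st)
      suppressWarnings(binary_corr(r$binaries[fr, ci[1]],
                                   r$binaries[fr, ci[2]]))
    }, numeric(1))
    out[st] <- mean(vals, na.rm = TRUE)
  }
  out
}
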