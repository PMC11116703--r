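#' One-way repeated-measures ANOVA over brain states
#'
#' Tests whether a subject x state variable (relative occurrence or Fisher-z
#' co-occurrence of a macro group) depends on the brain state, with STATE as
#' the single within-subject factor: `F` with `df = (s - 1, (s - 1)(n - 1))`
#' for `s` states and `n` subjects. Subjects with any missing state are
#' dropped listwise (with a message); no sphericity correction is applied.
#' A zero residual sum of squares is reported as a degenerate fit
#' (`F = NA`).
#'
#' @param table data frame with columns `subject`, `state`, `value`.
#' @return An object of class `wf_anova`: `F`, `df1`, `df2`, `p`,
#'   `n_subjects`, `n_states`, `dropped` and the aov `table`.
#' @export
rm_anova <- function(table) {
  stopifnot(all(c("subject", "state", "value") %in% names(table)))
  tab <- table
  tab$state <- factor(as.character(tab$state),
                      levels = intersect(wf_states(),
                                         unique(as.character(tab$state))))
  complete <- tapply(is.finite(tab$value), tab$subject, all)
  dropped <- names(complete)[!complete]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " subject(s) with missing states: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!tab$subject %in% dropped, ]
  }
  n <- length(unique(tab$subject)); s <- nlevels(droplevels(tab$state))
  if (n < 2 || s < 2) stop("need at least 2 subjects and 2 states")
  tab$subject <- factor(tab$subject)
  fit <- stats::aov(value ~ state + Error(subject / state), data = tab)
  st <- summary(fit)[["Error: subject:state"]][[1]]
  Fv <- st["state", "F value"]
  df1 <- st["state", "Df"]; df2 <- st["Residuals", "Df"]
  p <- st["state", "Pr(>F)"]
  ss_state <- st["state", "Sum Sq"]; ss_res <- st["Residuals", "Sum Sq"]
  degenerate <- !is.finite(Fv) ||
    ss_res <= 1e-12 * max(ss_state + ss_res, .Machine$double.xmin) ||
    ss_state + ss_res <= 1e-20 * sum(tab$value^2)
  if (degenerate) { Fv <- NA_real_; p <- NA_real_ }
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p, n_subjects = n,
                 n_states = s, dropped = dropped, table = st),
            class = "wf_anova")
}

#' @export
print.wf_anova <- function(x, ...) {
  if (is.na(x$F)) {
    cat("RM ANOVA: degenerate (zero residual variance), df = (",
        x$df1, ",", x$df2, ")\n")
  } else {
    cat(sprintf("RM ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
                x$df1, x$df2, x$F, x$p))
  }
  invisible(x)
}

#' Holm-corrected paired post hoc t-tests over state pairs
#'
#' Paired t-tests (df = n - 1) for every pair of states, with the Holm
#' step-down adjustment (monotonicity enforced) controlling the family-wise
#' error over all pairs.
#'
#' @param table data frame with `subject`, `state`, `value`; subjects with
#'   missing values in a pair are dropped for that pair.
#' @param pairs optional 2-column character matrix of state pairs; defaults
#'   to all pairs of observed states.
#' @return Data frame with `state_a`, `state_b`, `t`, `df`, `p_raw`,
#'   `p_holm`.
#' @export
posthoc_holm <- function(table, pairs = NULL) {
  states <- intersect(wf_states(), unique(as.character(table$state)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(states, 2))
  }
  res <- apply(pairs, 1, function(pr) {
    a <- table[table$state == pr[1], c("subject", "value")]
    b <- table[table$state == pr[2], c("subject", "value")]
    m <- merge(a, b, by = "subject")
    m <- m[is.finite(m$value.x) & is.finite(m$value.y), ]
    if (nrow(m) < 2) return(c(t = NA_real_, df = NA_real_, p = NA_real_))
    d <- m$value.x - m$value.y
    if (stats::sd(d) == 0) {
      return(c(t = 0, df = nrow(m) - 1, p = 1))
    }
    tt <- stats::t.test(m$value.x, m$value.y, paired = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  })
  out <- data.frame(state_a = pairs[, 1], state_b = pairs[, 2],
                    t = res["t", ], df = res["df", ], p_raw = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}
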