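#' Fit a group spatial ICA decomposition to multi-session recordings
#'
#' The core estimator: two-stage PCA reduction (per-session temporal
#' compression, then group-level compression of the concatenated reduced
#' data), spatial FastICA stabilized with ICASSO, and GICA back-reconstruction
#' of per-session maps and time courses. Group maps are z-scored over masked
#' pixels and sign-oriented so the pixel of maximum absolute weight is
#' positive; time courses carry the complementary (arbitrary ICA) scale.
#'
#' @param sessions list of `dff_movie` objects sharing an identical mask and
#'   pixel order; at least 2 for a group analysis.
#' @param k number of group components.
#' @param l1 first-stage retained dimension per session; default
#'   `ceiling(1.5 * k)`, capped by the session rank.
#' @param n_runs ICASSO runs (set `n_runs = 2` and `mode = "randinit"` for a
#'   quick fit).
#' @param mode ICASSO resampling mode, see [icasso()].
#' @param seed integer seed; the fit is deterministic given it.
#' @param max_iter,tol FastICA controls.
#' @return An object of class `wfica` with components
#'   \describe{
#'   \item{maps}{`k x P` group spatial ICs (z-scored).}
#'   \item{mixing}{`k x k` group mixing matrix (whitened space).}
#'   \item{sessions}{per session: `maps` (`k x P`), `timecourses`
#'     (`k x T_s`), ids and segments.}
#'   \item{icasso}{the `wf_icasso` stability result.}
#'   \item{reduction}{per-session and group whitening/dewhitening models.}
#'   \item{mask, pixel_idx, fps}{geometry shared by the sessions.}
#'   }
#' @seealso [select_order()] for choosing `k`, [match_components()] for
#'   comparing component sets, [single_session_ica()].
#' @export
wfica <- function(sessions, k, l1 = NULL, n_runs = 10L,
                  mode = c("both", "randinit", "bootstrap"), seed = 1L,
                  max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(length(sessions) >= 1, k >= 1)
  ref <- sessions[[1]]
  for (s in sessions[-1]) {
    if (!identical(s$mask, ref$mask)) stop("sessions have different masks")
  }
  l1 <- l1 %||% ceiling(1.5 * k)
  reduced <- lapply(sessions, function(s) {
    reduce_session(s, min(l1, min(dim(s$data))))
  })
  grp <- reduce_group(reduced, k)
  ica <- icasso(grp$Xw, k, n_runs = n_runs, mode = mode, seed = seed,
                max_iter = max_iter, tol = tol)
  S <- orient_maps(ica$maps)
  # mixing by least squares: Xw ~ A S  (centrotypes need not be an exact
  # joint unmixing of Xw)
  A <- grp$Xw %*% t(S) %*% solve(S %*% t(S))

  fit <- structure(list(
    maps = S, mixing = A, icasso = ica, k = as.integer(k),
    reduction = list(sessions = reduced, group = grp),
    mask = ref$mask, pixel_idx = ref$pixel_idx, fps = ref$fps,
    session_info = lapply(sessions, function(s)
      list(subject_id = s$subject_id, session_id = s$session_id,
           segments = s$segments)),
    seed = seed), class = "wfica")
  fit$sessions <- back_reconstruct(fit)
  fit
}

# flip each row so its max-|weight| pixel is positive; returns oriented maps
orient_maps <- function(S) {
  sgn <- apply(S, 1, function(m) sign(m[which.max(abs(m))]))
  sgn[sgn == 0] <- 1
  S * sgn
}

#' Back-reconstruct per-session maps and time courses
#'
#' GICA back-reconstruction: the group mixing is pushed back through the
#' stored two-stage dewhitening chain, giving for session `s` the time
#' courses `R_s = G_s %*% Ghat_s %*% A` (`T_s x k`) and per-session maps
#' `S_s = pinv(Ghat_s %*% A) %*% X_s` (`k x P`). Usually called internally
#' by [wfica()].
#'
#' @param fit a `wfica` object.
#' @return List (one element per session) with `maps`, `timecourses`
#'   (`k x T_s`), `subject_id`, `session_id`, `segments`.
#' @export
back_reconstruct <- function(fit) {
  stopifnot(inherits(fit, "wfica"))
  grp <- fit$reduction$group
  lapply(seq_along(fit$reduction$sessions), function(s) {
    red <- fit$reduction$sessions[[s]]
    Ghat_s <- grp$Ghat[grp$rows[[s]], , drop = FALSE]
    M <- Ghat_s %*% fit$mixing                    # L1 x k
    tc <- t(red$G %*% M)                          # k x T_s
    maps_s <- MASS::ginv(M) %*% red$X             # k x P
    info <- fit$session_info[[s]]
    list(maps = maps_s, timecourses = tc, subject_id = info$subject_id,
         session_id = info$session_id, segments = info$segments)
  })
}

#' Run single-session ICA in the group pixel space
#'
#' Reduces one session to `k` whitened dimensions and runs ICASSO-stabilized
#' FastICA on it alone — the reference decomposition that back-reconstructed
#' group components are validated against, session by session.
#'
#' @param session a `dff_movie`.
#' @param k number of components.
#' @inheritParams wfica
#' @return List with `maps` (`k x P`, z-scored, sign-oriented) and the
#'   `wf_icasso` result.
#' @export
single_session_ica <- function(session, k, n_runs = 10L,
                               mode = c("both", "randinit", "bootstrap"),
                               seed = 1L, max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  red <- reduce_session(session, k)
  ica <- icasso(red$X, k, n_runs = n_runs, mode = mode, seed = seed,
                max_iter = max_iter, tol = tol)
  list(maps = orient_maps(ica$maps), icasso = ica)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.wfica <- function(x, ...) {
  cat("Group spatial ICA fit:", x$k, "components,",
      length(x$sessions), "session(s),", ncol(x$maps), "pixels\n")
  cat("  ICASSO stability:",
      paste(sprintf("%.2f", x$icasso$stability), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.wfica <- function(object, atlas = NULL, ...) {
  peaks <- t(vapply(seq_len(object$k), function(i) {
    locate_peak(object$maps[i, ], object$mask)
  }, integer(2)))
  df <- data.frame(ic = seq_len(object$k), peak_row = peaks[, 1],
                   peak_col = peaks[, 2],
                   stability = round(object$icasso$stability, 3))
  if (!is.null(atlas)) {
    df$group <- vapply(seq_len(object$k), function(i)
      assign_group(peaks[i, ], atlas), character(1))
  }
  structure(list(table = df, k = object$k,
                 n_sessions = length(object$sessions),
                 r_index = object$icasso$r_index),
            class = "summary.wfica")
}

#' @export
print.summary.wfica <- function(x, ...) {
  cat("Group ICA:", x$k, "components over", x$n_sessions,
      "sessions; R-index", sprintf("%.4f", x$r_index), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract the group component maps
#'
#' @param object a `wfica` fit.
#' @param ... unused.
#' @return `k x P` matrix of z-scored spatial maps.
#' @export
coef.wfica <- function(object, ...) object$maps

#' Plot group component maps
#'
#' @param x a `wfica` fit.
#' @param components which components to draw (default all).
#' @param ... passed to [graphics::image()].
#' @export
plot.wfica <- function(x, components = seq_len(x$k), ...) {
  n <- length(components)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  H <- nrow(x$mask); W <- ncol(x$mask)
  for (i in components) {
    img <- matrix(NA_real_, H, W)
    img[x$pixel_idx] <- x$maps[i, ]
    graphics::image(seq_len(W), seq_len(H), t(img[H:1, ]), axes = FALSE,
                    xlab = "", ylab = "", main = paste0("IC", i),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  }
  invisible(x)
}
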