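#' ICASSO stability analysis of FastICA estimates
#'
#' Re-runs FastICA `n_runs` times — with fresh random initializations and/or
#' bootstrap resampling of the observations (pixels) — collects all component
#' estimates, clusters them by absolute spatial correlation (average-linkage
#' agglomerative clustering on `1 - |r|`), and returns one centrotype per
#' cluster: the estimate with the largest total similarity to the rest of
#' its cluster. Bootstrap runs are re-whitened and their unmixing applied to
#' the original data so every estimate lives in the same pixel space. The
#' first run always uses the original (un-resampled) data.
#'
#' @param Xw whitened `K x P` group matrix.
#' @param K number of components / clusters.
#' @param n_runs number of ICA runs (>= 2).
#' @param mode `"randinit"`, `"bootstrap"` or `"both"`.
#' @param seed integer seed driving all runs.
#' @param max_iter,tol passed to [fastica()].
#' @return An object of class `wf_icasso`: `maps` (centrotype estimates,
#'   `K x P`, z-scored over pixels), `stability` (per-cluster quality index,
#'   clipped to `[0, 1]`), `r_index` (scalar, see [r_index()]), `cluster`
#'   (assignment of all `n_runs * K` estimates), `centrotype` (their row
#'   indices), `estimates` (all estimates), `similarity`.
#' @export
icasso <- function(Xw, K, n_runs = 10L, mode = c("both", "randinit",
                                                 "bootstrap"),
                   seed = 1L, max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  if (n_runs < 2) stop("icasso needs n_runs >= 2")
  K <- as.integer(K)
  P <- ncol(Xw)
  est <- matrix(0, n_runs * K, P)
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      boot <- r > 1 && mode %in% c("bootstrap", "both")
      Xr <- Xw
      Wh <- diag(nrow(Xw))
      if (boot) {
        idx <- sample.int(P, P, replace = TRUE)
        Xb <- Xw[, idx, drop = FALSE]
        e <- eigen(Xb %*% t(Xb) / (P - 1), symmetric = TRUE)
        Wh <- diag(1 / sqrt(pmax(e$values, 1e-12)),
                   length(e$values)) %*% t(e$vectors)
        Xr <- Wh %*% Xb
      }
      fit <- suppressWarnings(
        fastica(Xr, W0 = matrix(stats::rnorm(nrow(Xw)^2), nrow(Xw)),
                max_iter = max_iter, tol = tol))
      est[(r - 1L) * K + seq_len(K), ] <-
        (fit$W %*% Wh %*% Xw)[seq_len(K), , drop = FALSE]
    }
  })
  sim <- abs(stats::cor(t(est)))
  diss <- 1 - sim
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, k = K)

  centro <- integer(K)
  stability <- numeric(K)
  n_est <- nrow(est)
  for (q in seq_len(K)) {
    members <- which(cl == q)
    within <- sim[members, members, drop = FALSE]
    centro[q] <- members[which.max(rowSums(within))]
    # compactness of the cluster: mean within-cluster similarity
    # (separation from other clusters is what the R-index measures)
    stability[q] <- if (length(members) > 1) {
      min(1, max(0, mean(within[upper.tri(within)])))
    } else 1
  }
  maps <- est[centro, , drop = FALSE]
  maps <- t(scale(t(maps)))               # z-score over pixels
  structure(list(maps = maps, stability = stability,
                 r_index = r_index(sim, cl), cluster = cl,
                 centrotype = centro, estimates = est, similarity = sim,
                 K = K, n_runs = n_runs, mode = mode, seed = seed),
            class = "wf_icasso")
}

#' @export
print.wf_icasso <- function(x, ...) {
  cat("ICASSO:", x$K, "clusters from", x$n_runs, "runs (", x$mode, ")\n")
  cat("  stability: ", paste(sprintf("%.2f", x$stability), collapse = " "),
      "\n  R-index: ", sprintf("%.4f", x$r_index), "\n", sep = "")
  invisible(x)
}

#' Cluster compactness/separation index for ICASSO clusterings
#'
#' For each cluster `q`, let `s_in(q)` be the mean pairwise similarity
#' (`|correlation|` between component estimates) inside the cluster
#' (1 for singletons) and `s_ex(q, q')` the mean similarity to another
#' cluster. The index is
#' `mean_q [ max_{q' != q} s_ex(q, q') / s_in(q) ]`:
#' the separation from the most-overlapping other cluster relative to the
#' cluster's own compactness. It is small when clusters are tight and
#' mutually distinct, grows when the order is too high (split clusters are
#' near-duplicates, `s_ex -> 1`) and when it is too low (under-order
#' estimates are mixtures that stay mutually correlated), and is minimized
#' over candidate model orders in [select_order()].
#'
#' @param sim symmetric similarity matrix (`|corr|`) of all estimates.
#' @param cluster integer cluster assignment.
#' @return Scalar index (finite, nonnegative).
#' @export
r_index <- function(sim, cluster) {
  ks <- sort(unique(cluster))
  ratio <- vapply(ks, function(q) {
    m <- which(cluster == q)
    s_in <- if (length(m) > 1) {
      sm <- sim[m, m, drop = FALSE]
      mean(sm[upper.tri(sm)])
    } else 1
    s_ex <- vapply(setdiff(ks, q), function(q2) {
      mean(sim[m, which(cluster == q2), drop = FALSE])
    }, numeric(1))
    max(s_ex) / max(s_in, 1e-9)
  }, numeric(1))
  mean(ratio)
}

#' Select the model order by minimizing the R-index
#'
#' Runs [icasso()] for every candidate number of components and returns the
#' candidate with the smallest [r_index()], together with the full curve.
#' The first-stage session reduction uses `L1 = ceiling(1.5 * max(K))`
#' (capped by the session rank) for all candidates.
#'
#' @param sessions list of `dff_movie` sharing a mask.
#' @param candidate_ks integer vector of candidate orders (warns when only
#'   one candidate is given).
#' @param n_runs ICASSO runs per candidate.
#' @param seed integer seed.
#' @return List with `k` (the selected order), `r_index` (named numeric
#'   curve), `stability` (list of per-cluster indices per candidate).
#' @export
select_order <- function(sessions, candidate_ks, n_runs = 10L, seed = 1L) {
  if (length(candidate_ks) < 1) stop("need at least one candidate K")
  if (length(candidate_ks) == 1) {
    warning("only one candidate order; returning it without comparison")
  }
  L1 <- ceiling(1.5 * max(candidate_ks))
  reduced <- lapply(sessions, function(s) {
    reduce_session(s, min(L1, min(dim(if (inherits(s, "dff_movie")) s$data
                                      else s))))
  })
  curve <- numeric(length(candidate_ks))
  stab <- vector("list", length(candidate_ks))
  for (i in seq_along(candidate_ks)) {
    K <- candidate_ks[i]
    grp <- reduce_group(reduced, K)
    res <- tryCatch(icasso(grp$Xw, K, n_runs = n_runs, seed = seed),
                    error = function(e) {
                      stop("icasso failed at K = ", K, ": ",
                           conditionMessage(e))
                    })
    curve[i] <- res$r_index
    stab[[i]] <- res$stability
  }
  names(curve) <- candidate_ks
  list(k = candidate_ks[which.min(curve)], r_index = curve, stability = stab)
}
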