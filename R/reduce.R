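#' First-stage temporal PCA reduction of one session
#'
#' Compresses a session's `T x P` dF/F0 matrix in the temporal domain to
#' `L1` whitened spatial patterns, via the eigendecomposition of the pixel
#' Gram matrix. The whitened output `X` (`L1 x P`) satisfies
#' `X %*% t(X) / (P - 1) = I` and the dewhitening matrix `G` (`T x L1`)
#' reconstructs the session on the retained subspace, `Y ~ G %*% X`.
#'
#' @param session a `dff_movie` (or a bare `T x P` matrix).
#' @param L1 retained dimension; must not exceed the data rank.
#' @return List with `X` (whitened, `L1 x P`), `G` (dewhitening, `T x L1`),
#'   `d` (retained eigenvalues of `t(Y) %*% Y`), `var_explained`.
#' @export
reduce_session <- function(session, L1) {
  Y <- if (inherits(session, "dff_movie")) session$data else session
  stopifnot(is.matrix(Y))
  P <- ncol(Y)
  if (L1 > min(dim(Y))) stop("L1 exceeds min(T, P)")
  C <- crossprod(Y)                       # P x P
  ev <- eigen(C, symmetric = TRUE)
  pos <- sum(ev$values > max(ev$values) * 1e-12)
  if (L1 > pos) stop("L1 (", L1, ") exceeds the data rank (", pos, ")")
  V <- ev$vectors[, seq_len(L1), drop = FALSE]
  X <- sqrt(P - 1) * t(V)
  G <- (Y %*% V) / sqrt(P - 1)
  list(X = X, G = G, d = ev$values[seq_len(L1)],
       var_explained = sum(ev$values[seq_len(L1)]) / sum(pmax(ev$values, 0)))
}

#' Second-stage (group) PCA reduction
#'
#' Stacks the whitened per-session matrices along the reduced-time dimension
#' and applies a second PCA to `K` dimensions, with the same whitening
#' contract as [reduce_session()]. The dewhitening matrix `Ghat`
#' (`sum(L1) x K`) carries group components back to the per-session reduced
#' spaces (`X_stack ~ Ghat %*% Xw`).
#'
#' @param reduced list of results from [reduce_session()].
#' @param K group dimension; at most the stacked dimension.
#' @return List with `Xw` (`K x P` whitened group matrix), `Ghat`, `rows`
#'   (per-session row ranges in the stack), `d`.
#' @export
reduce_group <- function(reduced, K) {
  Xs <- lapply(reduced, `[[`, "X")
  L1s <- vapply(Xs, nrow, integer(1))
  if (K > sum(L1s)) stop("K exceeds the stacked reduced dimension")
  Xstack <- do.call(rbind, Xs)
  r2 <- reduce_session(Xstack, K)         # PCA over the stacked dimension
  ends <- cumsum(L1s)
  rows <- Map(function(a, b) seq.int(a, b), ends - L1s + 1L, ends)
  list(Xw = r2$X, Ghat = r2$G, rows = rows, d = r2$d)
}
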