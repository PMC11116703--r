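#' FastICA with logcosh contrast and symmetric decorrelation
#'
#' Estimates a square unmixing matrix `W` for pre-whitened data `X`
#' (components x observations; here observations are pixels, i.e. spatial
#' ICA). Fixed-point iteration with the `log cosh` nonlinearity and
#' symmetric (simultaneous) decorrelation. Deterministic given `seed`.
#'
#' @param X whitened `K x P` matrix (`X %*% t(X) / (P - 1)` close to the
#'   identity).
#' @param seed integer seed for the random orthonormal initialization
#'   (ignored when `W0` is given).
#' @param W0 optional `K x K` initial unmixing matrix.
#' @param alpha logcosh slope parameter in `[1, 2]`.
#' @param max_iter,tol iteration controls; convergence is declared when the
#'   largest change in any component direction falls below `tol`.
#' @return List with `W` (unmixing), `S` (`W %*% X`, the component
#'   estimates), `converged`, `iterations`. A warning (not an error) is
#'   raised on non-convergence.
#' @export
fastica <- function(X, seed = 1L, W0 = NULL, alpha = 1,
                    max_iter = 200L, tol = 1e-6) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  K <- nrow(X); P <- ncol(X)
  W <- if (!is.null(W0)) W0 else
    with_seed(seed, matrix(stats::rnorm(K * K), K, K))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WX <- W %*% X
    g <- tanh(alpha * WX)
    gp <- alpha * (1 - g^2)
    W1 <- (g %*% t(X)) / P - diag(rowMeans(gp), K) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("fastica did not converge in ", max_iter, " iterations")
  }
  list(W = W, S = W %*% X, converged = converged, iterations = it)
}

# W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     length(e$values)) %*% t(e$vectors) %*% W
}
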