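#' Solve the rectangular assignment problem
#'
#' Maximum-weight injective matching of rows to columns (Hungarian/Munkres
#' algorithm on the square-padded cost matrix). With fewer columns than rows
#' some rows stay unmatched, and vice versa.
#'
#' @param score numeric matrix of assignment scores (higher is better).
#' @return Integer vector of length `nrow(score)`: the column assigned to
#'   each row, `NA` for unmatched rows.
#' @export
solve_assignment <- function(score) {
  stopifnot(is.matrix(score), all(is.finite(score)))
  n <- max(dim(score))
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(score)), seq_len(ncol(score))] <- max(score) - score
  a <- munkres(cost)
  out <- a[seq_len(nrow(score))]
  out[out > ncol(score)] <- NA_integer_
  out
}

# Munkres algorithm, minimizing total cost of a square matrix.
# Returns assigned column per row.
munkres <- function(cost) {
  n <- nrow(cost)
  eps <- 1e-9 * (1 + max(abs(cost)))
  C <- cost
  C <- C - apply(C, 1, min)
  C <- sweep(C, 2, apply(C, 2, min))
  starred <- matrix(FALSE, n, n)
  primed <- matrix(FALSE, n, n)
  row_cov <- rep(FALSE, n); col_cov <- rep(FALSE, n)
  # initial stars: greedy on zeros
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (C[i, j] <= eps && !any(starred[i, ]) && !any(starred[, j])) {
      starred[i, j] <- TRUE
    }
  }
  repeat {
    # step 3: cover starred columns
    col_cov <- apply(starred, 2, any)
    if (sum(col_cov) == n) break
    repeat {
      # step 4: find an uncovered zero
      z <- which(C <= eps & !row_cov[row(C)] & !col_cov[col(C)],
                 arr.ind = TRUE)
      if (nrow(z) == 0) {
        # step 6: adjust by the smallest uncovered value
        mn <- min(C[!row_cov, !col_cov, drop = FALSE])
        C[row_cov, ] <- C[row_cov, , drop = FALSE] + mn
        C[, !col_cov] <- C[, !col_cov, drop = FALSE] - mn
        next
      }
      i <- z[1, 1]; j <- z[1, 2]
      primed[i, j] <- TRUE
      sj <- which(starred[i, ])
      if (length(sj) == 0) {
        # step 5: augmenting path of alternating primes and stars
        path <- matrix(c(i, j), 1, 2)
        repeat {
          si <- which(starred[, path[nrow(path), 2]])
          if (length(si) == 0) break
          path <- rbind(path, c(si, path[nrow(path), 2]))
          pj <- which(primed[si, ])
          path <- rbind(path, c(si, pj[1]))
        }
        for (r in seq_len(nrow(path))) {
          ij <- path[r, ]
          starred[ij[1], ij[2]] <- !starred[ij[1], ij[2]]
        }
        primed[] <- FALSE
        row_cov[] <- FALSE; col_cov[] <- FALSE
        break
      } else {
        row_cov[i] <- TRUE
        col_cov[sj] <- FALSE
      }
    }
  }
  apply(starred, 1, which)
}

#' Match two component sets by rectangular assignment
#'
#' Computes the Pearson correlation matrix `R` between the rows of two map
#' sets (over shared pixels) and solves the maximum-`sum(|r|)` injective
#' assignment, so each component of `set_b` is used at most once. Signed
#' correlations are reported per matched pair.
#'
#' @param set_a,set_b component maps, `K_a x P` and `K_b x P`.
#' @return An object of class `wf_match`: `assignment` (column index in
#'   `set_b` per row of `set_a`, `NA` if unmatched), `r` (signed correlation
#'   per pair), `total` (sum of matched `|r|`), `R` (full correlation
#'   matrix).
#' @export
match_components <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) stop("empty component set")
  if (!is.matrix(set_a)) set_a <- matrix(set_a, nrow = 1)
  if (!is.matrix(set_b)) set_b <- matrix(set_b, nrow = 1)
  stopifnot(ncol(set_a) == ncol(set_b))
  R <- stats::cor(t(set_a), t(set_b))
  asg <- solve_assignment(abs(R))
  r <- vapply(seq_len(nrow(R)), function(i) {
    if (is.na(asg[i])) NA_real_ else R[i, asg[i]]
  }, numeric(1))
  structure(list(assignment = asg, r = r,
                 total = sum(abs(r), na.rm = TRUE), R = R),
            class = "wf_match")
}

#' @export
print.wf_match <- function(x, ...) {
  cat("Component matching:", sum(!is.na(x$assignment)), "pair(s), total |r| =",
      sprintf("%.3f", x$total), "\n")
  df <- data.frame(a = seq_along(x$assignment), b = x$assignment,
                   r = round(x$r, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
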