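#' Build a synthetic dorsal-cortex label atlas
#'
#' Constructs a bilaterally symmetric label image standing in for a
#' macro-area cortical parcellation: five macro groups (Somatomotor,
#' Somatosensory, PosteriorParietal, Visual, Retrosplenial) arranged
#' mirror-symmetrically about a contiguous midline column band, inside an
#' elliptical field-of-view mask. Bregma and lambda landmarks sit on the
#' midline band. Label 0 marks pixels outside the mask.
#'
#' Construction is deterministic given `seed`; the seed only jitters the
#' macro-group seed points slightly so repeated calls with the same seed give
#' identical label images.
#'
#' @param height,width image size in pixels; both must be >= 32.
#' @param seed integer seed for the (small) seed-point jitter.
#' @return An object of class `wf_atlas`: list with `labels` (height x width
#'   integer matrix), `legend` (named character, label -> macro group),
#'   `bregma`, `lambda` (integer `(row, col)`), `midline_cols` (integer
#'   vector of band columns) and `mask` (logical matrix, labels > 0).
#' @export
#' @examples
#' at <- make_atlas(64, 64, seed = 0)
#' table(at$legend[as.character(at$labels[at$labels > 0])])
make_atlas <- function(height, width, seed = 0L) {
  if (height < 32 || width < 32) {
    stop("atlas dimensions must be at least 32 x 32")
  }
  H <- as.integer(height); W <- as.integer(width)
  rc <- (H + 1) / 2; cc <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W)
  cw <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- ((rr - rc) / (0.46 * H))^2 + ((cw - cc) / (0.46 * W))^2 <= 1

  midline_cols <- which(abs(seq_len(W) - cc) <= 1.5)

  groups <- c("Somatomotor", "Somatosensory", "PosteriorParietal",
              "Visual", "Retrosplenial")
  # left-hemisphere seed points as (row, col) fractions of (H, W)
  pts <- rbind(
    Somatomotor       = c(0.28, 0.30),
    Somatosensory     = c(0.50, 0.20),
    PosteriorParietal = c(0.60, 0.36),
    Visual            = c(0.80, 0.30),
    Retrosplenial     = c(0.72, 0.43)
  )
  pts <- with_seed(seed, pts + matrix(stats::runif(10, -0.015, 0.015), 5, 2))

  labels <- matrix(0L, H, W)
  left <- which(mask & cw < min(midline_cols), arr.ind = TRUE)
  if (nrow(left) > 0) {
    d <- sapply(seq_len(nrow(pts)), function(k) {
      (left[, 1] / H - pts[k, 1])^2 + (left[, 2] / W - pts[k, 2])^2
    })
    lab <- max.col(-d, ties.method = "first")
    labels[left] <- lab
    # mirror to the right hemisphere: col -> W + 1 - col (exact symmetry)
    labels[cbind(left[, 1], W + 1L - left[, 2])] <- lab
  }
  band <- mask & cw %in% midline_cols
  labels[band] <- 6L
  # pixels inside the mask on the right that have no mirrored partner (none
  # by construction: the ellipse is symmetric about cc) stay 0

  legend <- c(`1` = "Somatomotor", `2` = "Somatosensory",
              `3` = "PosteriorParietal", `4` = "Visual",
              `5` = "Retrosplenial", `6` = "Midline")

  bregma <- c(row = as.integer(round(0.22 * H)), col = as.integer(floor(cc)))
  lambda <- c(row = as.integer(round(0.85 * H)), col = as.integer(floor(cc)))
  stopifnot(labels[bregma[1], bregma[2]] == 6L,
            labels[lambda[1], lambda[2]] == 6L)

  structure(list(labels = labels, legend = legend, bregma = bregma,
                 lambda = lambda, midline_cols = midline_cols,
                 mask = labels > 0L),
            class = "wf_atlas")
}

#' @export
print.wf_atlas <- function(x, ...) {
  cat("Synthetic cortical atlas:", nrow(x$labels), "x", ncol(x$labels),
      "px,", sum(x$mask), "labeled pixels\n")
  tab <- table(x$legend[as.character(x$labels[x$labels > 0])])
  for (nm in names(tab)) cat(sprintf("  %-18s %5d px\n", nm, tab[[nm]]))
  cat("  bregma (", x$bregma[1], ",", x$bregma[2], "), lambda (",
      x$lambda[1], ",", x$lambda[2], ")\n")
  invisible(x)
}

#' Look up the macro group of a pixel
#'
#' Returns the legend name of the atlas label at the given pixel — the rule
#' used to tag a component by the location of its peak weight. The label of
#' the exact pixel is used; no interpolation.
#'
#' @param peak integer `(row, col)` pixel.
#' @param atlas a `wf_atlas`.
#' @return Macro-group name (character scalar).
#' @export
assign_group <- function(peak, atlas) {
  lab <- atlas$labels[peak[1], peak[2]]
  if (lab == 0L) stop("peak pixel (", peak[1], ",", peak[2],
                      ") falls outside all atlas labels")
  unname(atlas$legend[as.character(lab)])
}
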