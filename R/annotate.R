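#' Locate a component's peak pixel
#'
#' Returns the masked pixel of maximum absolute weight — the location used to
#' tag a component with an atlas macro area, taken independently of the
#' weight's sign. Ties are broken by row-major order (first by row, then by
#' column).
#'
#' @param map numeric `P`-vector of weights over the masked pixels.
#' @param mask logical `H x W` matrix whose `TRUE` pixels (column-major
#'   order) correspond to `map`.
#' @return Integer `(row, col)` of the peak pixel.
#' @export
locate_peak <- function(map, mask) {
  stopifnot(all(is.finite(map)), length(map) == sum(mask))
  if (max(map) == min(map)) stop("constant map has no peak")
  idx <- which(mask)
  H <- nrow(mask)
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  a <- abs(map)
  cand <- which(a == max(a))
  best <- cand[order(r[cand], cc[cand])][1]
  c(row = r[best], col = cc[best])
}

#' Annotate components and flag artifacts
#'
#' Tags every component with the macro group of its peak pixel and flags
#' artifact components: a component is flagged `midline` when more than
#' `midline_frac` of its top-decile-|weight| pixels lie in the atlas midline
#' band, and `vessel` when its half-max support (pixels with `|w| >= 0.5
#' max|w|`) is elongated — square root of the ratio of the principal second
#' moments of the support coordinates — beyond `elongation` (cortical
#' parcels are compact, vessels are ridges). A manual exclusion list
#' overrides both.
#' Flagged components are not retained for downstream statistics.
#'
#' @param maps `K x P` component maps over the masked pixels.
#' @param atlas a `wf_atlas` on the same grid.
#' @param mask logical `H x W` mask matching `maps`.
#' @param midline_frac fraction threshold in `(0, 1]` (default 0.5).
#' @param elongation axis-ratio threshold `>= 1` (default 4).
#' @param manual integer ids to exclude regardless of the automatic rules.
#' @return Data frame (class `wf_labels`) with columns `ic_id`, `peak_row`,
#'   `peak_col`, `group`, `retained`, `reason`
#'   (`"midline"`, `"vessel"`, `"manual"` or `"none"`).
#' @export
flag_artifacts <- function(maps, atlas, mask, midline_frac = 0.5,
                           elongation = 4, manual = integer(0)) {
  stopifnot(midline_frac > 0, midline_frac <= 1, elongation >= 1)
  if (!is.matrix(maps)) maps <- matrix(maps, nrow = 1)
  idx <- which(mask)
  H <- nrow(mask)
  px_r <- (idx - 1L) %% H + 1L
  px_c <- (idx - 1L) %/% H + 1L
  in_band <- px_c %in% atlas$midline_cols
  out <- lapply(seq_len(nrow(maps)), function(i) {
    m <- abs(maps[i, ])
    peak <- locate_peak(maps[i, ], mask)
    grp <- assign_group(peak, atlas)
    top <- m >= stats::quantile(m, 0.9)
    reason <- "none"
    if (i %in% manual) {
      reason <- "manual"
    } else if (mean(in_band[top]) > midline_frac) {
      reason <- "midline"
    } else {
      supp <- m >= 0.5 * max(m)
      cov <- stats::cov(cbind(px_r[supp], px_c[supp]))
      ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
      if (sqrt(max(ev) / max(min(ev), 1e-9)) > elongation) reason <- "vessel"
    }
    data.frame(ic_id = i, peak_row = peak[1], peak_col = peak[2],
               group = grp, retained = reason == "none", reason = reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("wf_labels", class(res))
  res
}
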