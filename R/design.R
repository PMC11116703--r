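#' Source design for the synthetic study
#'
#' Defines the ground-truth sources of the synthetic wide-field study: their
#' spatial location (Gaussian blobs inside atlas macro groups), per-state
#' activation-event rates, and the co-activation coupling between a
#' designated "retrosplenial-like" source pair.
#'
#' The temporal design follows the emulated study conditions. The two
#' deepest states are bistable, with near-global up-states at 0.1-0.2
#' events/s shared by all sources; intermediate states are oscillatory
#' (jittered-periodic master events at 0.2-0.6 events/s) with a decreasing
#' fraction of each source's events locked to the master train (`sync`); the
#' awake state has fully asynchronous, independent transients. This makes
#' total activity increase while overall co-activation decreases from deep
#' anesthesia to wakefulness. Event rates are chosen so the retrosplenial
#' pair's share of total activity decreases monotonically deepest-to-awake.
#'
#' `coupling[i, j, s]` is the event-level co-activation probability of a
#' designed pair: the fraction of the lower-rate member's events that are
#' shared with the other member in state `s`. Default values for the
#' retrosplenial pair are calibrated with [calibrate_coupling()] so the phi
#' correlation of the binarized, thresholded time courses hits `target_phi`
#' per state (0.80 deepest to 0.35 awake by default).
#'
#' @param atlas a `wf_atlas` from [make_atlas()].
#' @param fps sampling rate in Hz the design is calibrated for.
#' @param amplitude per-source peak calcium transient, percent dF/F0.
#' @param sigma_px spatial Gaussian width (pixels).
#' @param tau calcium-kernel decay constant (s).
#' @param jitter half-width of the uniform per-event amplitude jitter
#'   (fraction of amplitude).
#' @param target_phi length-6 vector of designed phi coefficients for the
#'   retrosplenial pair, deepest state first.
#' @return An object of class `wf_design`: fields `n_sources`, `centers`
#'   (n x 2), `widths`, `macro_group`, `state_rate` (n x 6, events/min),
#'   `coupling` (n x n x 6), `amplitude`, plus the temporal-regime fields
#'   (`states`, `master_rate`, `sync`, `regime`, `tau`, `jitter`, `fps`,
#'   `pairs`).
#' @export
source_design <- function(atlas, fps = 40, amplitude = 5, sigma_px = 3.5,
                          tau = 0.5, jitter = 0.2,
                          target_phi = c(0.80, 0.70, 0.60, 0.50, 0.42, 0.35)) {
  states <- wf_states()
  stopifnot(length(target_phi) == length(states))
  # one blob per hemisphere for RSP / Somatomotor / Somatosensory, plus one
  # Visual (left) and one PosteriorParietal (right): 8 sources
  roster <- data.frame(
    group = c("Retrosplenial", "Retrosplenial", "Somatomotor", "Somatomotor",
              "Somatosensory", "Somatosensory", "Visual", "PosteriorParietal"),
    hemi = c("L", "R", "L", "R", "L", "R", "L", "R"),
    stringsAsFactors = FALSE)
  centers <- t(apply(roster, 1, function(r) {
    region_centroid(atlas, r[["group"]], r[["hemi"]])
  }))
  n <- nrow(roster)
  rsp <- which(roster$group == "Retrosplenial")

  # master-event rate per state (events/s); NA = no master train (awake)
  master_rate <- c(0.15, 0.18, 0.30, 0.45, 0.60, NA)
  # fraction of each source's events locked to the master train
  sync <- c(1.0, 0.85, 0.65, 0.45, 0.30, 0)
  regime <- c("bistable", "bistable", "oscillatory", "oscillatory",
              "oscillatory", "asynchronous")
  # events/min per source per state: retrosplenial share of total activity
  # decreases monotonically while total activity increases
  rate_rsp   <- c(7.2, 7.56, 9.9, 10.8, 11.4, 12.0)
  rate_other <- c(5.4, 8.0, 14.7, 24.3, 33.8, 48.0)
  rate <- matrix(rep(rate_other, each = n), n, length(states),
                 dimnames = list(NULL, states))
  rate[rsp, ] <- rep(rate_rsp, each = length(rsp))

  design <- structure(list(
    n_sources = n, centers = centers, widths = rep(sigma_px, n),
    macro_group = roster$group, hemi = roster$hemi,
    state_rate = rate, amplitude = rep(amplitude, n),
    states = states, master_rate = master_rate, sync = sync,
    regime = regime, tau = tau, jitter = jitter, fps = fps,
    pairs = list(rsp), coupling = NULL, target_phi = target_phi),
    class = "wf_design")

  design$coupling <- default_coupling(design)
  design$coupling[rsp[1], rsp[2], ] <- design$coupling[rsp[2], rsp[1], ] <-
    calibrate_coupling(design, rsp, target_phi)
  validate_design(design, atlas)
  design
}

# centroid of one hemisphere's share of a macro-group label, rounded to px
region_centroid <- function(atlas, group, hemi = c("L", "R")) {
  hemi <- match.arg(hemi)
  lab <- as.integer(names(atlas$legend)[atlas$legend == group])
  idx <- which(atlas$labels == lab, arr.ind = TRUE)
  keep <- if (hemi == "L") idx[, 2] < min(atlas$midline_cols)
          else idx[, 2] > max(atlas$midline_cols)
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) stop("no ", group, " pixels in hemisphere ", hemi)
  ctr <- round(colMeans(idx))
  # snap to a pixel inside the label
  if (atlas$labels[ctr[1], ctr[2]] != lab) {
    d <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    ctr <- idx[which.min(d), ]
  }
  as.integer(ctr)
}

validate_design <- function(design, atlas = NULL) {
  with(design, {
    stopifnot(all(state_rate >= 0), all(widths > 0), all(amplitude > 0))
    stopifnot(dim(coupling)[1] == n_sources, dim(coupling)[3] == length(states))
    for (s in seq_along(states)) {
      cs <- coupling[, , s]
      if (max(abs(cs - t(cs))) > 1e-12) stop("coupling not symmetric")
      if (any(diag(cs) != 1)) stop("coupling diagonal must be 1")
      if (any(cs < 0 | cs > 1)) stop("coupling outside [0, 1]")
    }
  })
  if (!is.null(atlas)) {
    for (k in seq_len(design$n_sources)) {
      if (atlas$labels[design$centers[k, 1], design$centers[k, 2]] == 0L) {
        stop("source ", k, " center lies outside the atlas labels")
      }
    }
  }
  invisible(design)
}

# designed co-activation for uncoupled pairs is 0: any co-activation they
# show comes from chance participation in the shared master train
default_coupling <- function(design) {
  n <- design$n_sources; S <- length(design$states)
  cp <- array(0, dim = c(n, n, S),
              dimnames = list(NULL, NULL, design$states))
  for (s in seq_len(S)) cp[, , s] <- diag(n) * 1 + (1 - diag(n)) * 0
  cp
}

#' Calibrate event-level coupling to a target phi coefficient
#'
#' Translates a designed phi correlation between the binarized (threshold at
#' 3 sigma of the deepest state) time courses of a source pair into the
#' event-level co-activation probability the generator samples from. The
#' calibration inverts the sparse-activation relation
#' `phi = (p11 - p_i p_j) / sqrt(p_i (1 - p_i) p_j (1 - p_j))`
#' using the forward model: deepest-state time-course variance from the
#' discrete Campbell theorem, the number of frames a jittered
#' exponential-decay transient spends above threshold, and the expected
#' frame overlap of two jointly triggered transients.
#'
#' @param design a `wf_design` (coupling may still be unset).
#' @param pair integer pair of source indices.
#' @param target_phi length-6 vector of phi targets, deepest state first.
#' @return Vector of co-activation probabilities per state (share of the
#'   lower-rate member's events that are co-activations), clipped to [0, 1].
#' @export
calibrate_coupling <- function(design, pair, target_phi) {
  fps <- design$fps; tau <- design$tau
  i <- pair[1]; j <- pair[2]
  th <- predicted_threshold(design, pair)
  nfr <- frames_above(design, pair, th)
  out <- numeric(length(target_phi))
  for (s in seq_along(target_phi)) {
    lam_i <- design$state_rate[i, s] / 60
    lam_j <- design$state_rate[j, s] / 60
    p_i <- lam_i / fps * nfr$En[1]
    p_j <- lam_j / fps * nfr$En[2]
    p11 <- target_phi[s] * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j)) +
      p_i * p_j
    lam11 <- p11 * fps / nfr$En_min
    out[s] <- min(1, max(0, lam11 / min(lam_i, lam_j)))
  }
  out
}

# predicted +/-3 sigma threshold of the deepest-state time course (discrete
# Campbell theorem, including the amplitude-jitter second moment)
predicted_threshold <- function(design, sources) {
  vapply(sources, function(k) {
    lam <- design$state_rate[k, 1] / 60
    m2 <- 1 + design$jitter^2 / 3
    v <- (lam / design$fps) * design$amplitude[k]^2 * m2 /
      (1 - exp(-2 / (design$fps * design$tau)))
    3 * sqrt(v)
  }, numeric(1))
}

# expected frames above threshold per transient, and expected overlap for a
# jointly triggered pair, averaging over the amplitude jitter
frames_above <- function(design, pair, th) {
  fps <- design$fps; tau <- design$tau
  nf <- function(a, t) ifelse(a > t, floor(fps * tau * log(a / t)) + 1, 0)
  u <- seq(-design$jitter, design$jitter, length.out = 41)
  n1 <- nf(design$amplitude[pair[1]] * (1 + u), th[1])
  n2 <- nf(design$amplitude[pair[2]] * (1 + u), th[2])
  list(En = c(mean(n1), mean(n2)), En_min = mean(outer(n1, n2, pmin)))
}

#' @export
print.wf_design <- function(x, ...) {
  cat("Synthetic source design:", x$n_sources, "sources\n")
  df <- data.frame(group = x$macro_group, hemi = x$hemi,
                   row = x$centers[, 1], col = x$centers[, 2],
                   round(x$state_rate, 1), check.names = FALSE)
  print(df, row.names = FALSE)
  cat("coupled pair(s):",
      paste(vapply(x$pairs, paste, "", collapse = "-"), collapse = ", "),
      "; target phi:", paste(x$target_phi, collapse = ", "), "\n")
  invisible(x)
}
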