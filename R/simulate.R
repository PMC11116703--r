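#' Simulate per-source calcium time courses and event trains
#'
#' Draws activation events for every source in every brain state according to
#' the design's temporal regime and renders them as calcium transients
#' (single-exponential decay kernel). Deep ("bistable") states share a global
#' Poisson up-state train that sources join probabilistically; intermediate
#' ("oscillatory") states use a jittered-periodic master train; the awake
#' ("asynchronous") state draws independent Poisson trains per source.
#' Designed source pairs have their event co-occurrence matched to the
#' design's coupling probabilities.
#'
#' Per-source, per-state event counts have expectation
#' `state_rate / 60 * dur_per_state`.
#'
#' @param design a `wf_design`.
#' @param states ordered character vector of states to simulate (deepest
#'   first); defaults to all six.
#' @param fps sampling rate, Hz.
#' @param dur_per_state duration of each state segment, seconds.
#' @param seed integer seed; the result is deterministic given it.
#' @return List with `timecourses` (n_sources x T matrix, percent dF/F0),
#'   `events` (per source, data.frame of event `time` (s, session clock),
#'   `amp`, `state`), `segments` (frame table) and `fps`.
#' @export
simulate_timecourses <- function(design, states = design$states,
                                 fps = design$fps, dur_per_state, seed = 1L) {
  if (length(states) == 0) stop("empty state list")
  if (dur_per_state <= 0) stop("negative or zero duration")
  if (fps <= 0) stop("fps must be positive")
  stopifnot(all(states %in% design$states))
  n <- design$n_sources
  T_state <- as.integer(round(dur_per_state * fps))
  segments <- make_segments(states, rep(T_state, length(states)))
  T_total <- max(segments$end)

  with_seed(seed, {
    events <- replicate(n, list(time = numeric(0), amp = numeric(0),
                                state = character(0)), simplify = FALSE)
    add_events <- function(k, t_local, amp, offset_s, state) {
      events[[k]]$time <<- c(events[[k]]$time, offset_s + t_local)
      events[[k]]$amp <<- c(events[[k]]$amp, amp)
      events[[k]]$state <<- c(events[[k]]$state, rep(state, length(t_local)))
    }

    for (si in seq_along(states)) {
      st <- states[si]
      sd_idx <- match(st, design$states)
      offset_s <- (segments$start[si] - 1L) / fps
      g <- design$master_rate[sd_idx]
      rates <- design$state_rate[, sd_idx] / 60   # events/s

      # designed shared-event rate per pair (events/s): coupling is the
      # co-activated share of the lower-rate member's events
      lam11 <- vapply(design$pairs, function(pr) {
        design$coupling[pr[1], pr[2], sd_idx] *
          min(rates[pr[1]], rates[pr[2]])
      }, numeric(1))
      priv <- rates          # private rates, reduced below
      part_events <- vector("list", n)   # per-source master event times

      if (!is.na(g)) {
        # master-event regime: every source locks a `sync` fraction of its
        # events to a shared global train
        times <- if (design$regime[sd_idx] == "bistable") {
          sort(stats::runif(stats::rpois(1, g * dur_per_state),
                            0, dur_per_state))
        } else {
          period <- 1 / g
          tt <- stats::runif(1, 0, period) +
            period * (0:ceiling(dur_per_state * g)) +
            stats::rnorm(ceiling(dur_per_state * g) + 1, 0, 0.15 * period)
          sort(tt[tt >= 0 & tt < dur_per_state])
        }
        ne <- length(times)
        pi_k <- pmin(1, design$sync[sd_idx] * rates / g)
        part <- matrix(stats::runif(ne * n) < rep(pi_k, each = ne), ne, n)
        res11 <- numeric(length(design$pairs))
        for (q in seq_along(design$pairs)) {
          pr <- design$pairs[[q]]; i <- pr[1]; j <- pr[2]
          # co-participation in the master train covers as much of the
          # designed shared rate as it can; the rest is a shared private train
          cc <- min(lam11[q] / max(g, 1e-12), min(pi_k[i], pi_k[j]))
          cc <- max(cc, max(0, pi_k[i] + pi_k[j] - 1))
          res11[q] <- max(0, lam11[q] - g * cc)
          u <- stats::runif(ne)
          part[, i] <- u < pi_k[i]
          pj_given <- ifelse(part[, i],
                             if (pi_k[i] > 0) cc / pi_k[i] else 0,
                             if (pi_k[i] < 1) (pi_k[j] - cc) / (1 - pi_k[i])
                             else 0)
          part[, j] <- stats::runif(ne) < pj_given
        }
        for (k in seq_len(n)) part_events[[k]] <- times[part[, k]]
        priv <- pmax(0, rates - g * pi_k)
        lam11 <- res11
      }
      # shared private trains for designed pairs
      for (q in seq_along(design$pairs)) {
        pr <- design$pairs[[q]]
        if (lam11[q] > 0) {
          ts <- stats::runif(stats::rpois(1, lam11[q] * dur_per_state),
                             0, dur_per_state)
          for (k in pr) {
            part_events[[k]] <- c(part_events[[k]], ts)
            priv[k] <- max(0, priv[k] - lam11[q])
          }
        }
      }
      # independent private events
      for (k in seq_len(n)) {
        tk <- c(part_events[[k]],
                stats::runif(stats::rpois(1, priv[k] * dur_per_state),
                             0, dur_per_state))
        if (length(tk) > 0) {
          tk <- sort(tk)
          amp <- design$amplitude[k] *
            (1 + stats::runif(length(tk), -design$jitter, design$jitter))
          add_events(k, tk, amp, offset_s, st)
        }
      }
    }

    tc <- matrix(0, n, T_total)
    L <- ceiling(6 * design$tau * fps)
    kern <- exp(-(0:L) / (fps * design$tau))
    for (k in seq_len(n)) {
      ev <- events[[k]]
      if (length(ev$time) == 0) next
      o <- order(ev$time)
      ev <- lapply(ev, `[`, o)
      events[[k]] <- ev
      f0 <- pmin(T_total, floor(ev$time * fps) + 1L)
      for (e in seq_along(f0)) {
        idx <- f0[e]:min(T_total, f0[e] + L)
        tc[k, idx] <- tc[k, idx] + ev$amp[e] * kern[seq_along(idx)]
      }
    }
    list(timecourses = tc,
         events = lapply(events, function(e)
           data.frame(time = e$time, amp = e$amp, state = e$state,
                      stringsAsFactors = FALSE)),
         segments = segments, fps = fps)
  })
}

# unit-peak Gaussian blob restricted to the atlas mask, as an H*W vector
gaussian_map <- function(center, sigma, atlas) {
  H <- nrow(atlas$labels); W <- ncol(atlas$labels)
  rr <- matrix(seq_len(H), H, W)
  cw <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- exp(-((rr - center[1])^2 + (cw - center[2])^2) / (2 * sigma^2))
  m[!atlas$mask] <- 0
  as.vector(m)
}

# elongated vessel-like static map: a streak from near bregma running
# posterolaterally across one hemisphere, ~1.5 px wide, unit peak
vessel_map <- function(atlas) {
  H <- nrow(atlas$labels); W <- ncol(atlas$labels)
  p0 <- c(atlas$bregma[1] + 0.08 * H, max(atlas$midline_cols) + 1)
  p1 <- c(0.80 * H, 0.82 * W)
  rr <- matrix(seq_len(H), H, W)
  cw <- matrix(seq_len(W), H, W, byrow = TRUE)
  v <- p1 - p0; L2 <- sum(v^2)
  tproj <- pmin(1, pmax(0, ((rr - p0[1]) * v[1] + (cw - p0[2]) * v[2]) / L2))
  d2 <- (rr - (p0[1] + tproj * v[1]))^2 + (cw - (p0[2] + tproj * v[2]))^2
  m <- exp(-d2 / (2 * 0.75^2))
  m[!atlas$mask] <- 0
  as.vector(m)
}

#' Assemble the ground truth for one synthetic session
#'
#' Bundles the design, the session's simulated time courses and event trains,
#' the true spatial maps, and the nuisance (noise, drift, vessel) parameters.
#'
#' @param atlas a `wf_atlas`.
#' @param design a `wf_design`.
#' @param dur_per_state seconds per state.
#' @param fps sampling rate, Hz.
#' @param seed integer seed for the event sampling.
#' @param noise_sd Gaussian sensor noise sd, camera counts.
#' @param drift list with `amp_sin` (percent), `freq` (Hz, < 0.05),
#'   `amp_lin` (percent over the session); set amplitudes to 0 to disable.
#' @param vessel_sd temporal sd of the vessel artifact (percent dF/F0);
#'   0 disables the artifact.
#' @param amp_scale multiplicative amplitude factor (subject variability).
#' @return An object of class `wf_truth` with `maps` (n_sources x H*W,
#'   unit-peak rows), `timecourses`, `events`, `segments`, `design`,
#'   `noise_sd`, `drift`, `vessel` and `atlas`.
#' @export
make_truth <- function(atlas, design, dur_per_state, fps = design$fps,
                       seed = 1L, noise_sd = 1,
                       drift = list(amp_sin = 1.5, freq = 0.02, amp_lin = 1),
                       vessel_sd = 0.5, amp_scale = 1) {
  sim <- simulate_timecourses(design, fps = fps,
                              dur_per_state = dur_per_state, seed = seed)
  maps <- t(vapply(seq_len(design$n_sources), function(k) {
    gaussian_map(design$centers[k, ], design$widths[k], atlas)
  }, numeric(length(atlas$labels))))
  structure(list(maps = maps, timecourses = amp_scale * sim$timecourses,
                 events = sim$events, segments = sim$segments, fps = fps,
                 design = design, atlas = atlas, noise_sd = noise_sd,
                 drift = drift, vessel = list(map = vessel_map(atlas),
                                              sd = vessel_sd),
                 seed = seed),
            class = "wf_truth")
}

#' Render a synthetic fluorescence movie from ground truth
#'
#' Forward model: `F[t, p] = f0 * (1 + (sum_k maps[k, p] * tc[k, t] + drift_t
#' + vessel_p * vessel_t) / 100) + noise`, with a global multiplicative
#' low-frequency drift (sinusoid below 0.05 Hz plus a linear term), a static
#' vessel map with high-frequency temporal noise, and i.i.d. Gaussian sensor
#' noise. Landmarks and state segments are embedded in the returned movie.
#'
#' @param truth a `wf_truth` from [make_truth()].
#' @param f0 baseline fluorescence, counts; must be positive.
#' @param seed integer seed for noise and nuisance draws.
#' @param subject_id,session_id identifiers stored in the movie.
#' @return A `raw_movie` (see [raw_movie()]).
#' @export
render_movie <- function(truth, f0 = 100, seed = 1L,
                         subject_id = "s1", session_id = "r1") {
  if (f0 <= 0) stop("f0 must be positive")
  H <- nrow(truth$atlas$labels); W <- ncol(truth$atlas$labels)
  Tt <- ncol(truth$timecourses)
  if (ncol(truth$maps) != H * W) stop("maps/atlas shape mismatch")

  sig <- crossprod(truth$maps, truth$timecourses)   # (H*W) x T, percent
  with_seed(seed, {
    tt <- (seq_len(Tt) - 1) / truth$fps
    dr <- truth$drift
    drift_t <- dr$amp_sin * sin(2 * pi * dr$freq * tt +
                                  stats::runif(1, 0, 2 * pi)) +
      dr$amp_lin * (tt / max(tt[Tt], 1) - 0.5)
    if (truth$vessel$sd > 0) {
      ves_t <- stats::rnorm(Tt, 0, truth$vessel$sd)
      sig <- sig + outer(truth$vessel$map, ves_t)
    }
    sig <- sweep(sig, 2, drift_t, `+`)
    Fmat <- f0 * (1 + sig / 100)
    if (truth$noise_sd > 0) {
      Fmat <- Fmat + stats::rnorm(length(Fmat), 0, truth$noise_sd)
    }
    raw_movie(array(Fmat, dim = c(H, W, Tt)), fps = truth$fps,
              bregma = truth$atlas$bregma, lambda = truth$atlas$lambda,
              segments = truth$segments, subject_id = subject_id,
              session_id = session_id)
  })
}

#' Define a multi-subject synthetic study
#'
#' Sets up the full study layout — shared atlas and source design, one truth
#' object per session (3 subjects x 2 sessions by default, six states per
#' session) — without materializing the movies. Sessions are rendered on
#' demand with [study_session()], so only one full movie needs to be held in
#' memory at a time. Subjects differ by a global amplitude factor.
#'
#' Defaults are the emulated study conditions: 64 x 64 px, 40 Hz, 5 min per
#' state, six states deepest-to-awake.
#'
#' @param n_subjects,sessions_per_subject study layout.
#' @param height,width image size, px.
#' @param fps sampling rate, Hz.
#' @param dur_per_state seconds per state segment.
#' @param seed master integer seed; all per-session seeds derive from it.
#' @param noise_sd sensor noise sd (counts).
#' @param f0 baseline fluorescence (counts).
#' @param design optional `wf_design`; built from the atlas by default.
#' @param drift,vessel_sd nuisance settings passed to [make_truth()].
#' @return An object of class `wf_study`: `atlas`, `design`, `truths` (list
#'   of `wf_truth`), `subject` / `session_id` vectors, `n_sessions`, `f0`.
#' @export
simulate_study <- function(n_subjects = 3, sessions_per_subject = 2,
                           height = 64, width = 64, fps = 40,
                           dur_per_state = 300, seed = 1L, noise_sd = 1,
                           f0 = 100, design = NULL,
                           drift = list(amp_sin = 1.5, freq = 0.02,
                                        amp_lin = 1),
                           vessel_sd = 0.5) {
  atlas <- make_atlas(height, width, seed = 0L)
  if (is.null(design)) design <- source_design(atlas, fps = fps)
  n_sessions <- n_subjects * sessions_per_subject
  subject <- rep(seq_len(n_subjects), each = sessions_per_subject)
  amp_scale <- seq(0.9, 1.1, length.out = n_subjects)[subject]
  truths <- lapply(seq_len(n_sessions), function(i) {
    make_truth(atlas, design, dur_per_state = dur_per_state, fps = fps,
               seed = seed * 100L + i, noise_sd = noise_sd, drift = drift,
               vessel_sd = vessel_sd, amp_scale = amp_scale[i])
  })
  structure(list(atlas = atlas, design = design, truths = truths,
                 subject = paste0("m", subject),
                 session_id = paste0("m", subject, "_r",
                                     stats::ave(subject, subject,
                                                FUN = seq_along)),
                 n_sessions = n_sessions, seed = seed, f0 = f0),
            class = "wf_study")
}

#' Render one session of a synthetic study
#'
#' @param study a `wf_study`.
#' @param i session index, 1..`study$n_sessions`.
#' @return A `raw_movie`.
#' @export
study_session <- function(study, i) {
  stopifnot(i >= 1, i <= study$n_sessions)
  render_movie(study$truths[[i]], f0 = study$f0,
               seed = study$seed * 100L + 50L + i,
               subject_id = study$subject[i],
               session_id = study$session_id[i])
}

#' @export
print.wf_study <- function(x, ...) {
  cat("Synthetic wide-field study:", x$n_sessions, "sessions (",
      length(unique(x$subject)), "subjects ),",
      nrow(x$atlas$labels), "x", ncol(x$atlas$labels), "px,",
      x$truths[[1]]$fps, "Hz,",
      nrow(x$truths[[1]]$segments), "states x",
      round(diff(unlist(x$truths[[1]]$segments[1, c("start", "end")])) /
              x$truths[[1]]$fps / 60 + 1 / x$truths[[1]]$fps / 60, 2),
      "min\n")
  invisible(x)
}
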