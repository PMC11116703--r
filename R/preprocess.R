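#' Construct a raw fluorescence movie
#'
#' A session's fluorescence stack with its landmarks and brain-state segment
#' table. Frames are stored as an `H x W x T` array; the segment table holds
#' 1-based inclusive frame ranges, disjoint and ordered deepest-to-awake.
#'
#' @param frames numeric `H x W x T` array of nonnegative intensities.
#' @param fps sampling rate, Hz (default 40).
#' @param bregma,lambda landmark pixel coordinates `(row, col)`.
#' @param segments data.frame with columns `state`, `start`, `end`.
#' @param subject_id,session_id identifiers.
#' @return An object of class `raw_movie`.
#' @export
raw_movie <- function(frames, fps = 40, bregma, lambda, segments,
                      subject_id = "", session_id = "") {
  stopifnot(length(dim(frames)) == 3, fps > 0)
  check_segments(segments, dim(frames)[3])
  structure(list(frames = frames, fps = fps,
                 bregma = as.numeric(bregma), lambda = as.numeric(lambda),
                 segments = segments, subject_id = subject_id,
                 session_id = session_id),
            class = "raw_movie")
}

#' @export
print.raw_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("raw_movie", x$session_id, ":", d[1], "x", d[2], "px,", d[3],
      "frames @", x$fps, "Hz,", nrow(x$segments), "state segment(s)\n")
  invisible(x)
}

#' Register a movie to reference landmarks
#'
#' Applies the similarity transform (translation, rotation, isotropic scale —
#' 4 degrees of freedom, determined exactly by the bregma/lambda pair) that
#' carries the movie's landmarks onto the reference landmarks, to every
#' frame, with bilinear interpolation. If the landmarks already coincide with
#' the reference the movie is returned unchanged (identity short-circuit).
#'
#' @param movie a `raw_movie`.
#' @param ref_bregma,ref_lambda reference landmark coordinates `(row, col)`.
#' @return A registered `raw_movie` whose landmarks equal the reference.
#' @export
register <- function(movie, ref_bregma, ref_lambda) {
  b <- movie$bregma; l <- movie$lambda
  if (sum((b - l)^2) < 1e-12) stop("bregma and lambda coincide: degenerate transform")
  if (sum((ref_bregma - ref_lambda)^2) < 1e-12) {
    stop("reference landmarks coincide: degenerate transform")
  }
  if (max(abs(b - ref_bregma), abs(l - ref_lambda)) < 1e-9) {
    return(movie)  # identity
  }
  # similarity z' = s R z + t mapping (b, l) -> (ref_b, ref_l); represent
  # points as complex row + i*col, so z' = a z + t with complex a, t
  z1 <- complex(real = b[1], imaginary = b[2])
  z2 <- complex(real = l[1], imaginary = l[2])
  w1 <- complex(real = ref_bregma[1], imaginary = ref_bregma[2])
  w2 <- complex(real = ref_lambda[1], imaginary = ref_lambda[2])
  a <- (w1 - w2) / (z1 - z2)
  t_ <- w1 - a * z1
  # inverse map: source coords of each output pixel
  d <- dim(movie$frames); H <- d[1]; W <- d[2]; Tt <- d[3]
  wz <- complex(real = rep(seq_len(H), W),
                imaginary = rep(seq_len(W), each = H))
  src <- (wz - t_) / a
  sr <- Re(src); sc <- Im(src)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
  r0c <- pmin(pmax(r0, 1), H - 1); c0c <- pmin(pmax(c0, 1), W - 1)
  i00 <- (c0c - 1) * H + r0c
  w00 <- (1 - fr) * (1 - fc); w10 <- fr * (1 - fc)
  w01 <- (1 - fr) * fc;       w11 <- fr * fc
  Fm <- matrix(movie$frames, H * W, Tt)
  out <- w00 * Fm[i00, , drop = FALSE] + w10 * Fm[i00 + 1, , drop = FALSE] +
    w01 * Fm[i00 + H, , drop = FALSE] + w11 * Fm[i00 + H + 1, , drop = FALSE]
  out[!ok, ] <- 0
  movie$frames <- array(out, dim = d)
  movie$bregma <- as.numeric(ref_bregma)
  movie$lambda <- as.numeric(ref_lambda)
  movie
}

#' Spatially downsample a movie by block averaging
#'
#' Each output pixel is the mean of its `factor x factor` input block;
#' landmarks are rescaled by `1/factor`. If the dimensions are not divisible
#' by `factor` the bottom/right remainder is cropped.
#'
#' @param movie a `raw_movie`.
#' @param factor integer block size (default 4).
#' @return The downsampled `raw_movie`.
#' @export
downsample <- function(movie, factor = 4L) {
  factor <- as.integer(factor)
  if (factor <= 0) stop("factor must be a positive integer")
  if (factor == 1L) return(movie)
  d <- dim(movie$frames)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  if (H2 < 1 || W2 < 1) stop("factor larger than image")
  x <- movie$frames[seq_len(H2 * factor), seq_len(W2 * factor), , drop = FALSE]
  dim(x) <- c(factor, H2, factor * W2 * d[3])
  x <- colMeans(x)                       # H2 x (factor*W2*T)
  dim(x) <- c(H2, factor, W2 * d[3])
  x <- colMeans(aperm(x, c(2, 1, 3)))    # H2 x (W2*T)
  movie$frames <- array(x, dim = c(H2, W2, d[3]))
  movie$bregma <- (movie$bregma - 0.5) / factor + 0.5
  movie$lambda <- (movie$lambda - 0.5) / factor + 0.5
  movie
}

#' Intersect per-session valid regions into a common mask
#'
#' @param valid list of `H x W` logical matrices (one per session), all on
#'   the same registered reference grid.
#' @return Logical `H x W` mask: the pixelwise AND. Errors if empty.
#' @export
common_mask <- function(valid) {
  stopifnot(length(valid) >= 1)
  m <- Reduce(`&`, valid)
  if (!any(m)) stop("common mask is empty: sessions share no valid pixels")
  m
}

#' Compute percent dF/F0 over a pixel mask
#'
#' `data[t, p] = 100 * (F[t, p] - F0[p]) / F0[p]` with `F0` the per-pixel
#' temporal mean over the whole session. Masked pixels must have `F0 > 0`.
#'
#' @param movie a `raw_movie`.
#' @param mask logical `H x W` matrix selecting the pixels to keep.
#' @return An object of class `dff_movie`: `data` (`T x P` matrix, percent),
#'   `mask`, `pixel_idx` (column-major linear indices of the mask, fixing the
#'   pixel order), `f0`, `fps`, `segments`, ids.
#' @export
compute_dff <- function(movie, mask) {
  d <- dim(movie$frames)
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  pixel_idx <- which(mask)
  Fm <- matrix(movie$frames, d[1] * d[2], d[3])[pixel_idx, , drop = FALSE]
  f0 <- rowMeans(Fm)
  if (any(f0 <= 0)) stop("F0 <= 0 at ", sum(f0 <= 0), " masked pixel(s)")
  data <- 100 * t((Fm - f0) / f0)
  structure(list(data = data, mask = mask, pixel_idx = pixel_idx, f0 = f0,
                 fps = movie$fps, segments = movie$segments,
                 subject_id = movie$subject_id, session_id = movie$session_id),
            class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  cat("dff_movie", x$session_id, ":", nrow(x$data), "frames x",
      ncol(x$data), "pixels @", x$fps, "Hz,", nrow(x$segments),
      "state segment(s)\n")
  invisible(x)
}

# 4th-order Butterworth high-pass, zero phase, applied per pixel column in
# the frequency domain (squared-magnitude response = forward-backward
# filtering) with reflection padding; chunked over columns to bound memory.
zero_phase_highpass <- function(x, fps, cutoff, order = 4L, chunk = 256L) {
  bf <- signal::butter(order, cutoff / (fps / 2), type = "high")
  b <- bf$b; a <- bf$a
  n <- nrow(x)
  npad <- min(n - 1L, max(30L, ceiling(3 * fps / cutoff / 10)))
  ne <- n + 2L * npad
  z <- exp(1i * 2 * pi * (seq_len(ne) - 1) / ne)
  num <- outer(z, 0:(length(b) - 1), function(zz, k) zz^(-k)) %*% b
  den <- outer(z, 0:(length(a) - 1), function(zz, k) zz^(-k)) %*% a
  G <- as.vector(Mod(num / den)^2)
  out <- x
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, ncol(x))
    xs <- x[, jj, drop = FALSE]
    pre <- 2 * matrix(xs[1, ], npad, length(jj), byrow = TRUE) -
      xs[seq(npad + 1L, 2L), , drop = FALSE]
    post <- 2 * matrix(xs[n, ], npad, length(jj), byrow = TRUE) -
      xs[seq(n - 1L, n - npad), , drop = FALSE]
    y <- Re(stats::mvfft(stats::mvfft(rbind(pre, xs, post)) * G,
                         inverse = TRUE)) / ne
    out[, jj] <- y[seq(npad + 1L, npad + n), , drop = FALSE]
  }
  out
}

#' High-pass filter a dF/F0 movie
#'
#' Zero-phase 4th-order Butterworth high-pass applied independently to every
#' pixel trace. DC is rejected (gain < 1e-3) while the passband (e.g. 1 Hz at
#' a 0.1 Hz cutoff) is within 5% of unit gain. No explicit low-pass is
#' applied: the upper band edge is set by the Nyquist frequency.
#'
#' @param dff a `dff_movie`.
#' @param cutoff high-pass cutoff, Hz (default 0.1).
#' @return The filtered `dff_movie`.
#' @export
highpass <- function(dff, cutoff = 0.1) {
  if (cutoff >= dff$fps / 2) stop("cutoff must be below the Nyquist frequency")
  if (dff$fps <= 2 * cutoff) stop("fps too low for the requested cutoff")
  x <- zero_phase_highpass(dff$data, dff$fps, cutoff)
  # remove the residual per-pixel mean left by the finite-window edges so
  # the filtered traces are exactly DC-free
  dff$data <- sweep(x, 2, colMeans(x))
  dff
}

#' Concatenate per-state dF/F0 movies in time
#'
#' Stacks the inputs along the time axis (order as given, deepest state
#' first) and records each state's frame range in the segment table. All
#' inputs must share the mask, pixel order and sampling rate.
#'
#' @param per_state list of `dff_movie` objects, one per state, each with a
#'   single-segment table.
#' @return A single concatenated `dff_movie`.
#' @export
concatenate_states <- function(per_state) {
  stopifnot(length(per_state) >= 1)
  ref <- per_state[[1]]
  for (m in per_state[-1]) {
    if (!identical(m$mask, ref$mask) ||
        !identical(m$pixel_idx, ref$pixel_idx)) stop("mask mismatch")
    if (m$fps != ref$fps) stop("fps mismatch")
  }
  lens <- vapply(per_state, function(m) nrow(m$data), integer(1))
  states <- vapply(per_state, function(m) m$segments$state[1], character(1))
  ref$data <- do.call(rbind, lapply(per_state, `[[`, "data"))
  ref$segments <- make_segments(states, lens)
  ref
}

#' Preprocess one raw session into an analysis-ready dF/F0 matrix
#'
#' Runs the standard chain: spatial downsampling (block mean), registration
#' to reference landmarks, percent dF/F0 against the session-mean baseline,
#' and zero-phase high-pass filtering, over a common pixel mask.
#'
#' @param movie a `raw_movie`.
#' @param mask logical matrix on the downsampled, registered grid.
#' @param ref_bregma,ref_lambda reference landmarks on that grid; defaults to
#'   the movie's own landmarks (no-op registration).
#' @param factor spatial downsampling factor.
#' @param cutoff high-pass cutoff, Hz.
#' @return A `dff_movie`.
#' @export
preprocess_session <- function(movie, mask, ref_bregma = NULL,
                               ref_lambda = NULL, factor = 1L, cutoff = 0.1) {
  movie <- downsample(movie, factor)
  movie <- register(movie, ref_bregma %||% movie$bregma,
                    ref_lambda %||% movie$lambda)
  highpass(compute_dff(movie, mask), cutoff)
}
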