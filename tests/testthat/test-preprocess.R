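test_that("registration short-circuits when landmarks already match", {
  mv <- flat_movie()
  mv$frames[] <- array(rnorm(prod(dim(mv$frames))), dim(mv$frames))
  out <- register(mv, mv$bregma, mv$lambda)
  expect_identical(out$frames, mv$frames)
})

test_that("registration undoes a known landmark translation", {
  H <- 24; W <- 24; Tt <- 3
  set.seed(1)
  base <- array(rnorm(H * W * Tt), dim = c(H, W, Tt))
  shifted <- array(0, dim = c(H, W, Tt))
  shifted[4:H, , ] <- base[1:(H - 3), , ]      # content moved down 3 rows
  mv <- raw_movie(shifted, fps = 10, bregma = c(8 + 3, 12),
                  lambda = c(18 + 3, 12),
                  segments = make_segments("iso2.0", Tt))
  out <- register(mv, c(8, 12), c(18, 12))
  expect_equal(out$bregma, c(8, 12))
  # interior pixels equal the unshifted content
  expect_lt(max(abs(out$frames[5:(H - 5), 5:(W - 5), ] -
                      base[5:(H - 5), 5:(W - 5), ])), 1e-9)
})

test_that("registration applies rotation and scale exactly at landmarks", {
  mv <- flat_movie(24, 24, 2)
  set.seed(2)
  mv$frames[] <- rnorm(length(mv$frames))
  mv$bregma <- c(6, 10); mv$lambda <- c(18, 14)
  out <- register(mv, c(5, 12), c(19, 12))
  expect_equal(out$bregma, c(5, 12))
  expect_equal(out$lambda, c(19, 12))
  expect_error(register(flat_movie(), c(4, 8), c(4, 8)), "degenerate")
  bad <- flat_movie(); bad$bregma <- bad$lambda
  expect_error(register(bad, c(4, 8), c(13, 8)), "degenerate")
})

test_that("downsampling is an exact block mean", {
  mv <- flat_movie(8, 8, 2, value = 7)
  expect_identical(downsample(mv, 1L), mv)
  d4 <- downsample(mv, 4L)
  expect_equal(dim(d4$frames), c(2, 2, 2))
  expect_equal(unique(as.vector(d4$frames)), 7)
  # checkerboard, factor 2 -> everywhere 0.5
  cb <- flat_movie(8, 8, 1)
  cb$frames[, , 1] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(unique(as.vector(downsample(cb, 2L)$frames[, , 1])), 0.5)
  # non-divisible dimensions are cropped bottom/right
  odd <- flat_movie(9, 10, 1)
  expect_equal(dim(downsample(odd, 4L)$frames)[1:2], c(2, 2))
  expect_error(downsample(mv, 0L), "positive")
})

test_that("common_mask is the intersection of valid regions", {
  a <- matrix(FALSE, 6, 6); a[1:4, ] <- TRUE
  b <- matrix(FALSE, 6, 6); b[3:6, ] <- TRUE
  expect_equal(sum(common_mask(list(a, a))), sum(a))
  m <- common_mask(list(a, b))
  expect_equal(which(m, arr.ind = TRUE)[, 1] %in% 3:4, rep(TRUE, 12))
  cc <- matrix(FALSE, 6, 6); cc[5:6, ] <- TRUE
  expect_error(common_mask(list(a[, , drop = FALSE] & !a, cc)), "empty")
})

test_that("dF/F0 matches its defining formula", {
  mv <- flat_movie(8, 8, 10, value = 100)
  mask <- matrix(TRUE, 8, 8)
  expect_equal(max(abs(compute_dff(mv, mask)$data)), 0)
  mv$frames[3, 3, 5] <- 110
  d <- compute_dff(mv, mask)
  p <- match((3 - 1) * 8 + 3, d$pixel_idx)
  f0 <- (100 * 9 + 110) / 10
  expect_equal(d$data[5, p], 100 * (110 - f0) / f0)
  # random movie: elementwise agreement with the formula
  set.seed(3)
  mv$frames[] <- 100 + rnorm(length(mv$frames))
  d <- compute_dff(mv, mask)
  Fm <- t(matrix(mv$frames, 64, 10)[d$pixel_idx, ])
  expect_equal(d$data, 100 * sweep(sweep(Fm, 2, colMeans(Fm)), 2,
                                   colMeans(Fm), `/`),
               tolerance = 1e-12)
  bad <- flat_movie(8, 8, 4, value = 0)
  expect_error(compute_dff(bad, mask), "F0")
})

test_that("high-pass filter rejects DC and slow drift, passes the band", {
  fps <- 10; Tt <- 6000
  t <- (seq_len(Tt) - 1) / fps
  x <- cbind(rep(5, Tt), sin(2 * pi * 1 * t), sin(2 * pi * 0.01 * t))
  d <- structure(list(data = x, mask = matrix(TRUE, 1, 3),
                      pixel_idx = 1:3, f0 = rep(100, 3), fps = fps,
                      segments = make_segments("iso2.0", Tt)),
                 class = "dff_movie")
  out <- highpass(d, 0.1)$data
  tr <- 500:(Tt - 500)
  amp <- function(y, f) {
    X <- cbind(sin(2 * pi * f * t[tr]), cos(2 * pi * f * t[tr]))
    sqrt(sum(coef(lm(y[tr] ~ X - 1))^2))
  }
  expect_lt(max(abs(out[, 1])) / 5, 1e-3)          # DC gain
  expect_gt(amp(out[, 2], 1), 0.95)                # 1 Hz in the passband
  expect_lt(amp(out[, 2], 1), 1.05)
  expect_lt(amp(out[, 3], 0.01), 0.1)              # far below cutoff
  expect_error(highpass(d, 6), "Nyquist")
})

test_that("matrix filter agrees with signal::filtfilt on interior samples", {
  fps <- 10; Tt <- 4000
  set.seed(4)
  x <- matrix(rnorm(Tt * 3), Tt, 3)
  d <- structure(list(data = x, mask = matrix(TRUE, 1, 3), pixel_idx = 1:3,
                      f0 = rep(100, 3), fps = fps,
                      segments = make_segments("iso2.0", Tt)),
                 class = "dff_movie")
  ours <- highpass(d, 0.1)$data
  bf <- signal::butter(4, 0.1 / (fps / 2), type = "high")
  ref <- signal::filtfilt(bf, x[, 2])
  i <- 300:(Tt - 300)
  expect_lt(max(abs((ours[i, 2] - mean(ours[i, 2])) -
                      (ref[i] - mean(ref[i])))), 0.01)
  expect_gt(cor(ours[i, 2], ref[i]), 0.9999)
})

test_that("state concatenation is exact bookkeeping", {
  mk <- function(st, Tt, fill) {
    structure(list(data = matrix(fill, Tt, 4), mask = matrix(TRUE, 2, 2),
                   pixel_idx = 1:4, f0 = rep(1, 4), fps = 10,
                   segments = make_segments(st, Tt)), class = "dff_movie")
  }
  one <- concatenate_states(list(mk("iso2.0", 5, 1)))
  expect_equal(dim(one$data), c(5, 4))
  expect_equal(one$segments$end, 5L)
  two <- concatenate_states(list(mk("iso2.0", 5, 1), mk("iso1.75", 7, 2)))
  expect_equal(nrow(two$data), 12)
  expect_equal(two$segments$start, c(1L, 6L))
  expect_equal(two$segments$end, c(5L, 12L))
  # six-state round trip is bit-exact
  parts <- Map(mk, wf_states(), 3:8, 1:6)
  cat6 <- concatenate_states(unname(parts))
  for (i in seq_along(parts)) {
    seg <- cat6$segments[i, ]
    expect_identical(cat6$data[seg$start:seg$end, ], parts[[i]]$data)
  }
  badmask <- mk("iso1.5", 3, 0); badmask$mask[1] <- FALSE
  expect_error(concatenate_states(list(mk("iso2.0", 3, 1), badmask)),
               "mask")
})

test_that("the preprocessing chain is deterministic", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 3, fps = 10, seed = 5)
  mv <- render_movie(tr, f0 = 100, seed = 6)
  a <- preprocess_session(mv, at$mask)
  b <- preprocess_session(mv, at$mask)
  expect_identical(a$data, b$data)
})

test_that("high-pass filtering brings traces closer to drift-free truth", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 60, fps = 10, seed = 7,
                   noise_sd = 0.2,
                   drift = list(amp_sin = 3, freq = 0.02, amp_lin = 2))
  mv <- render_movie(tr, f0 = 100, seed = 8)
  dff <- compute_dff(mv, at$mask)
  hp <- highpass(dff, 0.1)
  pk <- which.max(tr$maps[1, at$mask])
  truth <- tr$timecourses[1, ]
  truth_hp <- truth - mean(truth)
  expect_gt(cor(hp$data[, pk], truth_hp), cor(dff$data[, pk], truth_hp))
})
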