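test_that("session reduction is lossless at full rank and whitened", {
  set.seed(1)
  A <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 50), 3, 50)
  r <- reduce_session(A, 3)
  expect_lt(norm(r$G %*% r$X - A, "F") / norm(A, "F"), 1e-8)
  P <- ncol(A)
  expect_lt(max(abs(r$X %*% t(r$X) / (P - 1) - diag(3))), 1e-6)
  expect_error(reduce_session(A, 10), "rank|min")
})

test_that("retained variance follows the eigenspectrum", {
  # two equal-variance orthogonal signals: L1 = 1 keeps half the variance
  t <- seq_len(400)
  Y <- 3 * cbind(sin(2 * pi * t / 50)) %*% t(rep(1, 100) * c(1, -1)) +
    3 * cbind(cos(2 * pi * t / 50)) %*% t(rep(1, 100) * c(1, 1))
  Y <- Y + matrix(rnorm(length(Y), 0, 1e-6), nrow(Y))
  r <- reduce_session(Y, 1)
  expect_equal(r$var_explained, 0.5, tolerance = 1e-3)
})

test_that("group reduction obeys the same whitening contract", {
  set.seed(2)
  sessions <- lapply(1:3, function(i) matrix(rnorm(60 * 80), 60, 80))
  red <- lapply(sessions, reduce_session, L1 = 6)
  grp <- reduce_group(red, 5)
  P <- 80
  expect_lt(max(abs(grp$Xw %*% t(grp$Xw) / (P - 1) - diag(5))), 1e-6)
  expect_equal(dim(grp$Ghat), c(18L, 5L))
  expect_error(reduce_group(red, 30), "exceeds")
})

test_that("two-stage projection is idempotent on the retained subspace", {
  set.seed(3)
  sessions <- lapply(1:2, function(i) matrix(rnorm(50 * 70), 50, 70))
  red <- lapply(sessions, reduce_session, L1 = 8)
  grp <- reduce_group(red, 6)
  Xstack <- do.call(rbind, lapply(red, `[[`, "X"))
  proj <- grp$Ghat %*% grp$Xw          # dewhiten
  reproj <- reduce_session(proj, 6)    # project again
  expect_lt(norm(reproj$G %*% reproj$X - proj, "F") / norm(proj, "F"), 1e-6)
})

test_that("fastica separates super-Gaussian sources", {
  set.seed(4)
  P <- 2000
  S <- rbind(rexp(P) * rbinom(P, 1, 0.2), rexp(P) * rbinom(P, 1, 0.2),
             rexp(P) * rbinom(P, 1, 0.2))
  A <- matrix(rnorm(9), 3, 3)
  X <- A %*% S
  wh <- reduce_session(X, 3)   # whiten via the same PCA machinery
  fit <- fastica(wh$X, seed = 1)
  m <- match_components(fit$S, S)
  expect_true(all(abs(m$r) > 0.95))
  expect_true(fit$converged)
})

test_that("fastica is deterministic and pixel-permutation equivariant", {
  set.seed(5)
  P <- 600
  X <- matrix(rnorm(16), 4, 4) %*%
    (matrix(rexp(4 * P), 4, P) * matrix(rbinom(4 * P, 1, 0.2), 4, P))
  wh <- reduce_session(X, 4)$X
  f1 <- fastica(wh, seed = 9)
  f2 <- fastica(wh, seed = 9)
  expect_identical(f1$S, f2$S)
  perm <- sample(ncol(wh))
  f3 <- fastica(wh[, perm], W0 = f1$W)
  # equivariant up to the per-component sign indeterminacy
  expect_equal(abs(f3$S[, order(perm)]), abs(f1$S), tolerance = 1e-3)
})

test_that("icasso clusters stable sources tightly", {
  set.seed(6)
  P <- 1500
  S <- rbind(rexp(P) * rbinom(P, 1, 0.15), rexp(P) * rbinom(P, 1, 0.15),
             rexp(P) * rbinom(P, 1, 0.15))
  X <- matrix(rnorm(9), 3, 3) %*% S
  wh <- reduce_session(X, 3)$X
  res <- icasso(wh, 3, n_runs = 5, seed = 1)
  expect_true(all(res$stability > 0.95))
  expect_true(all(res$r_index > 0))
  expect_true(is.finite(res$r_index))
  # every cluster holds one estimate per run
  expect_equal(as.integer(table(res$cluster)), rep(5L, 3))
  expect_error(icasso(wh, 3, n_runs = 1), "n_runs")
  # maps are z-scored over pixels
  expect_equal(apply(res$maps, 1, mean), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(res$maps, 1, sd), rep(1, 3), tolerance = 1e-10)
})

test_that("select_order warns on a single candidate and returns it", {
  set.seed(7)
  sessions <- lapply(1:2, function(i) matrix(rnorm(40 * 60), 40, 60))
  expect_warning(os <- select_order(sessions, 3, n_runs = 2, seed = 1),
                 "one candidate")
  expect_equal(os$k, 3)
  expect_true(all(is.finite(os$r_index)) && all(os$r_index > 0))
})

test_that("back-reconstruction collapses for a single session at full order", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 30, fps = 10, seed = 8)
  mv <- render_movie(tr, f0 = 100, seed = 9)
  dff <- preprocess_session(mv, at$mask)
  fit <- wfica(list(dff), k = 2, l1 = 2, n_runs = 3, seed = 1)
  m <- match_components(fit$sessions[[1]]$maps, fit$maps)
  expect_true(all(abs(m$r) > 1 - 1e-6))
})

test_that("flipping a group map's sign flips its session time courses", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 20, fps = 10, seed = 10)
  mv <- render_movie(tr, f0 = 100, seed = 11)
  dff <- preprocess_session(mv, at$mask)
  fit <- wfica(list(dff), k = 2, n_runs = 3, seed = 2)
  flipped <- fit
  flipped$maps[1, ] <- -flipped$maps[1, ]
  flipped$mixing[, 1] <- -flipped$mixing[, 1]
  br <- back_reconstruct(flipped)
  expect_equal(br[[1]]$timecourses[1, ], -fit$sessions[[1]]$timecourses[1, ])
  expect_equal(br[[1]]$timecourses[2, ], fit$sessions[[1]]$timecourses[2, ])
})

test_that("noiseless multi-session recovery returns matched time courses", {
  at <- tiny_atlas()
  d <- two_source_design()
  dff <- lapply(1:2, function(i) {
    tr <- make_truth(at, d, dur_per_state = 60, fps = 10, seed = i,
                     noise_sd = 0.05,
                     drift = list(amp_sin = 0, freq = 0.02, amp_lin = 0),
                     vessel_sd = 0)
    preprocess_session(render_movie(tr, f0 = 100, seed = 20 + i), at$mask)
  })
  fit <- wfica(dff, k = 2, n_runs = 3, seed = 3)
  for (s in 1:2) {
    tr <- make_truth(at, d, dur_per_state = 60, fps = 10, seed = s,
                     noise_sd = 0.05,
                     drift = list(amp_sin = 0, freq = 0.02, amp_lin = 0),
                     vessel_sd = 0)
    # compare against the band-limited truth: the analysis chain only sees
    # the high-passed signal, and slow deep-state event trains have genuine
    # sub-cutoff power
    truth_tc <- t(wfgica:::zero_phase_highpass(t(tr$timecourses), 10, 0.1))
    est_tc <- fit$sessions[[s]]$timecourses
    m <- match_components(truth_tc, est_tc)
    expect_true(all(abs(m$r) > 0.95))
  }
})
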