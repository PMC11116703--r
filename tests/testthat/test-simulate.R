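test_that("zero rates give all-zero time courses and no events", {
  d <- two_source_design()
  d$state_rate[] <- 0
  sim <- simulate_timecourses(d, fps = 10, dur_per_state = 30, seed = 1)
  expect_equal(max(abs(sim$timecourses)), 0)
  expect_equal(sum(vapply(sim$events, nrow, integer(1))), 0L)
})

test_that("perfect coupling gives identical event trains", {
  d <- two_source_design()
  d$state_rate[2, ] <- d$state_rate[1, ]
  d$coupling[1, 2, ] <- d$coupling[2, 1, ] <- 1
  sim <- simulate_timecourses(d, states = "iso2.0", fps = 10,
                              dur_per_state = 120, seed = 4)
  expect_gt(nrow(sim$events[[1]]), 0)
  expect_equal(sim$events[[1]]$time, sim$events[[2]]$time)
})

test_that("asynchronous event counts match the designed rate", {
  # Poisson oracle: rate 12/min for 300 s => mean 60, SE sqrt(60/n_seeds)
  d <- two_source_design()
  d$state_rate[, "awake"] <- 12
  d$coupling[1, 2, ] <- d$coupling[2, 1, ] <- 0
  n_seeds <- 50
  counts <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_timecourses(d, states = "awake", fps = 10,
                                dur_per_state = 300, seed = s)
    nrow(sim$events[[1]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / n_seeds))
})

test_that("per-state event counts track the design across regimes", {
  d <- two_source_design()
  mats <- vapply(1:20, function(s) {
    sim <- simulate_timecourses(d, fps = 10, dur_per_state = 120, seed = s)
    vapply(d$states, function(st)
      sum(sim$events[[1]]$state == st), numeric(1))
  }, numeric(6))
  expected <- d$state_rate[1, ] * 2       # events per 120 s
  se <- sqrt(expected / 20)
  expect_true(all(abs(rowMeans(mats) - expected) < 4 * se))
})

test_that("phi of binarized trains increases with the coupling parameter", {
  d <- two_source_design()
  phis <- vapply(c(0.2, 0.5, 0.9), function(cc) {
    d$coupling[1, 2, ] <- d$coupling[2, 1, ] <- cc
    mean(vapply(1:5, function(s) {
      sim <- simulate_timecourses(d, fps = 10, dur_per_state = 300, seed = s)
      tc <- sim$timecourses
      b1 <- { th <- compute_thresholds(tc[1, ], sim$segments)
              binarize(tc[1, ], th[1], th[2]) }
      b2 <- { th <- compute_thresholds(tc[2, ], sim$segments)
              binarize(tc[2, ], th[1], th[2]) }
      fr <- segment_frames(sim$segments, "awake")
      cor(b1[fr], b2[fr])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("designed phi targets are recovered from true time courses", {
  at <- tiny_atlas()
  d <- source_design(at, fps = 10)
  pair <- d$pairs[[1]]
  phis <- vapply(1:8, function(s) {
    sim <- simulate_timecourses(d, fps = 10, dur_per_state = 300, seed = s)
    tc <- sim$timecourses
    b <- lapply(pair, function(k) {
      th <- compute_thresholds(tc[k, ], sim$segments)
      binarize(tc[k, ], th[1], th[2])
    })
    vapply(d$states, function(st) {
      fr <- segment_frames(sim$segments, st)
      cor(b[[1]][fr], b[[2]][fr])
    }, numeric(1))
  }, numeric(6))
  expect_true(all(abs(rowMeans(phis) - d$target_phi) < 0.1))
})

test_that("the forward model renders exactly what it says", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 2, fps = 10, seed = 1,
                   noise_sd = 0, drift = list(amp_sin = 0, freq = 0.02,
                                              amp_lin = 0), vessel_sd = 0)
  # all-zero time courses -> constant movie at f0
  tr0 <- tr; tr0$timecourses[] <- 0
  mv0 <- render_movie(tr0, f0 = 100, seed = 1)
  expect_equal(max(abs(mv0$frames - 100)), 0)
  # a 10% transient at one frame reads 10% after dF/F0 at the source peak
  tr1 <- tr0
  tr1$timecourses[1, 60] <- 10
  mv1 <- render_movie(tr1, f0 = 100, seed = 1)
  dff <- compute_dff(mv1, at$mask)
  pk <- which(tr1$maps[1, at$mask] == 1)
  f0_px <- mean(100 * (1 + tr1$maps[1, at$mask][pk] *
                         tr1$timecourses[1, ] / 100))
  expected <- 100 * (100 * 1.10 - f0_px) / f0_px
  expect_equal(dff$data[60, pk], expected, tolerance = 1e-10)
  expect_error(render_movie(tr1, f0 = -5), "positive")
})

test_that("two seeds differ only in the noise realization", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 2, fps = 10, seed = 1,
                   drift = list(amp_sin = 0, freq = 0.02, amp_lin = 0),
                   vessel_sd = 0)
  m1 <- render_movie(tr, f0 = 100, seed = 1)
  m2 <- render_movie(tr, f0 = 100, seed = 2)
  m1b <- render_movie(tr, f0 = 100, seed = 1)
  expect_identical(m1$frames, m1b$frames)       # deterministic given seed
  resid <- m1$frames - m2$frames                # signal cancels exactly
  expect_equal(mean(resid), 0, tolerance = 0.05)
  expect_equal(sd(resid), sqrt(2) * tr$noise_sd, tolerance = 0.05)
})

test_that("dF/F0 round-trips the noiseless forward model", {
  at <- tiny_atlas()
  d <- two_source_design()
  tr <- make_truth(at, d, dur_per_state = 5, fps = 10, seed = 2,
                   noise_sd = 0, drift = list(amp_sin = 0, freq = 0.02,
                                              amp_lin = 0), vessel_sd = 0)
  mv <- render_movie(tr, f0 = 100, seed = 1)
  dff <- compute_dff(mv, at$mask)
  truth_sig <- t(crossprod(tr$maps[, at$mask, drop = FALSE],
                           tr$timecourses))
  # invert the stated forward model: F = (1 + dff/100) * F0, sig = F/f0 - 1
  Fhat <- sweep(1 + dff$data / 100, 2, dff$f0, `*`)
  recon_sig <- 100 * (Fhat / 100 - 1)
  expect_lt(sqrt(mean((recon_sig - truth_sig)^2)), 1e-6)
})
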