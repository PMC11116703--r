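# Shared fixtures. Everything is generated in code; heavier shared objects
# are memoized in this environment so several test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_atlas <- function() fixture("tiny_atlas", function() make_atlas(32, 32, 0))

# study + full analysis at the compact scale used for repeated-seed checks
small_study <- function(seed, dur = 120, hw = 40) {
  simulate_study(height = hw, width = hw, fps = 10, dur_per_state = dur,
                 seed = seed)
}

# a two-source design on the tiny atlas whose fields tests can modify
two_source_design <- function(fps = 10) {
  at <- tiny_atlas()
  d <- source_design(at, fps = fps)
  keep <- d$pairs[[1]]                  # the coupled retrosplenial pair
  d$n_sources <- 2L
  d$centers <- d$centers[keep, , drop = FALSE]
  d$widths <- d$widths[keep]
  d$macro_group <- d$macro_group[keep]
  d$hemi <- d$hemi[keep]
  d$state_rate <- d$state_rate[keep, , drop = FALSE]
  d$amplitude <- d$amplitude[keep]
  d$coupling <- d$coupling[keep, keep, , drop = FALSE]
  d$pairs <- list(c(1L, 2L))
  d
}

# quick raw movie with uniform baseline and a known segment layout
flat_movie <- function(H = 16, W = 16, Tt = 24, value = 100, fps = 10) {
  raw_movie(array(value, dim = c(H, W, Tt)), fps = fps,
            bregma = c(4, 8), lambda = c(13, 8),
            segments = make_segments("iso2.0", Tt))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
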