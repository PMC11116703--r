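test_that("phi coefficient handles the canonical binary cases", {
  expect_equal(binary_corr(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(binary_corr(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  # 2x2 contingency oracle: phi = (n11 n00 - n10 n01) / sqrt(prod margins)
  x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
  n11 <- sum(x & y); n00 <- sum(!x & !y)
  n10 <- sum(x & !y); n01 <- sum(!x & y)
  phi <- (n11 * n00 - n10 * n01) /
    sqrt(sum(x) * sum(!x) * sum(y) * sum(!y))
  expect_equal(binary_corr(x, y), phi)
  expect_equal(phi, 0)
  expect_warning(out <- binary_corr(c(1, 1, 1), c(1, 0, 1)), "constant")
  expect_true(is.na(out))
})

test_that("state matrices are symmetric with unit diagonal", {
  seg <- make_segments(c("iso2.0", "awake"), c(30, 10000))
  set.seed(1)
  B <- matrix(0L, 10030, 3)
  B[1:30, 1] <- B[1:30, 2] <- rep(c(1L, 0L), 15)   # identical, nonconstant
  B[31:10030, ] <- matrix(rbinom(30000, 1, 0.2), ncol = 3)
  mats <- state_matrices(B, seg)
  expect_equal(mats[["iso2.0"]][1, 2], 1)          # identical vectors
  expect_true(is.na(mats[["iso2.0"]][1, 3]))       # constant third IC
  aw <- mats[["awake"]]
  expect_equal(aw, t(aw))
  expect_equal(diag(aw), rep(1, 3))
  expect_lt(max(abs(aw[upper.tri(aw)])), 0.05) # independent vectors
  # invariance under IC reordering
  perm <- c(3, 1, 2)
  mats_p <- state_matrices(B[, perm], seg)
  expect_equal(mats_p[["awake"]], aw[perm, perm], tolerance = 1e-12)
})

test_that("Fisher-z group mean matches the arctanh oracle", {
  labels <- data.frame(ic_id = 1:3, peak_row = 1, peak_col = 1,
                       group = "Retrosplenial", retained = TRUE,
                       reason = "none")
  R0 <- diag(3)
  expect_equal(unname(fisher_group_mean(R0, labels, "Retrosplenial")["z"]), 0)
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.8
  labels2 <- labels[1:2, ]
  z <- fisher_group_mean(R[1:2, 1:2], labels2, "Retrosplenial")
  expect_equal(unname(z["z"]), atanh(0.8), tolerance = 1e-12)
  expect_equal(unname(z["r"]), 0.8, tolerance = 1e-12)
  # antisymmetric pair averages to zero
  R2 <- diag(3); R2[1, 2] <- R2[2, 1] <- 0.5
  R2[1, 3] <- R2[3, 1] <- -0.5; R2[2, 3] <- R2[3, 2] <- 0
  expect_equal(unname(fisher_group_mean(R2, labels, "Retrosplenial")["z"]),
               atanh(0.5) / 3 + atanh(-0.5) / 3)
  # exact-coincidence clipping keeps z finite
  R3 <- matrix(1, 2, 2)
  expect_true(is.finite(fisher_group_mean(R3, labels2,
                                          "Retrosplenial")["z"]))
  # fewer than two ICs -> missing
  expect_true(is.na(fisher_group_mean(R, labels[1, , drop = FALSE],
                                      "Retrosplenial")["z"]))
})

test_that("RM ANOVA matches the sums-of-squares oracle", {
  set.seed(2)
  tab <- expand.grid(subject = paste0("m", 1:3), state = wf_states(),
                     stringsAsFactors = FALSE)
  tab$value <- rnorm(nrow(tab)) + rep(seq(0, 1, length.out = 6), each = 3)
  a <- rm_anova(tab)
  # oracle: manual within-subject decomposition
  Y <- matrix(tab$value[order(tab$state, tab$subject)], 3, 6)
  gm <- mean(Y)
  ss_state <- 3 * sum((colMeans(Y) - gm)^2)
  ss_subj <- 6 * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_state - ss_subj
  F_oracle <- (ss_state / 5) / (ss_err / 10)
  expect_equal(a$F, F_oracle, tolerance = 1e-10)
  expect_equal(c(a$df1, a$df2), c(5, 10))
  expect_equal(a$p, pf(F_oracle, 5, 10, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate RM ANOVA inputs are reported, not hidden", {
  # perfectly additive 3x3 table: zero residual -> degenerate
  tab <- expand.grid(subject = paste0("m", 1:3),
                     state = c("iso2.0", "iso1.75", "iso1.5"),
                     stringsAsFactors = FALSE)
  tab$value <- as.numeric(match(tab$subject, paste0("m", 1:3)) +
                            match(tab$state, c("iso2.0", "iso1.75",
                                               "iso1.5")))
  a <- rm_anova(tab)
  expect_true(is.na(a$F) || !is.finite(a$F))
  expect_equal(c(a$df1, a$df2), c(2, 4))
  # all-identical values likewise
  tab$value <- 1
  a2 <- rm_anova(tab)
  expect_true(is.na(a2$F))
  expect_error(rm_anova(tab[tab$subject == "m1", ]), "at least 2")
})

test_that("subjects with missing states are dropped listwise", {
  tab <- expand.grid(subject = paste0("m", 1:3), state = wf_states(),
                     stringsAsFactors = FALSE)
  set.seed(3)
  tab$value <- rnorm(18) + as.integer(factor(tab$state))
  tab$value[tab$subject == "m3" & tab$state == "awake"] <- NA
  expect_message(a <- rm_anova(tab), "dropping 1 subject")
  expect_equal(a$n_subjects, 2)
  expect_equal(c(a$df1, a$df2), c(5, 5))
})

test_that("Holm adjustment matches the step-down oracle", {
  holm_oracle <- function(p) {
    o <- order(p)
    adj <- pmin(1, (length(p) - seq_along(p) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(length(p)); out[o] <- adj
    out
  }
  p <- c(0.01, 0.03, 0.04)
  expect_equal(holm_oracle(p), c(0.03, 0.06, 0.06))
  expect_equal(p.adjust(p, "holm"), holm_oracle(p))
  # end-to-end: paired t p-values from a table agree with manual holm
  set.seed(4)
  tab <- expand.grid(subject = paste0("m", 1:4),
                     state = c("iso2.0", "iso1.0", "awake"),
                     stringsAsFactors = FALSE)
  tab$value <- rnorm(12) + as.integer(factor(tab$state))
  ph <- posthoc_holm(tab)
  expect_equal(ph$p_holm, holm_oracle(ph$p_raw))
  expect_equal(nrow(ph), 3)
  expect_equal(unique(ph$df), 3)
  # a single pair is returned unadjusted
  ph1 <- posthoc_holm(tab, pairs = matrix(c("iso2.0", "awake"), 1))
  expect_equal(ph1$p_holm, ph1$p_raw)
  # identical paired samples: t = 0, p = 1
  tab2 <- tab; tab2$value <- rep(1:4, 3)
  ph2 <- posthoc_holm(tab2)
  expect_equal(ph2$t, rep(0, 3))
  expect_equal(ph2$p_raw, rep(1, 3))
})
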