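# Build an aligned object with a planted step response per neuron/trial.
planted_aligned <- function(steps, n_trials = 20, noise = 0.05, fs = 20,
                            types = NULL, seed = 1) {
  set.seed(seed)
  n <- length(steps)
  ntime <- 4 * fs
  time <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  data <- array(rnorm(n * ntime * n_trials, 0, noise), c(n, ntime, n_trials))
  for (i in seq_len(n)) {
    data[i, time >= 0, ] <- data[i, time >= 0, ] + steps[i]
  }
  toy_aligned(data, time, types %||% rep("Hit", n_trials), fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("classify_response detects planted activation and suppression", {
  al <- planted_aligned(c(0.3, -0.3, 0))
  expect_equal(classify_response(al, 1, "Hit")$direction, "activated")
  expect_equal(classify_response(al, 2, "Hit")$direction, "suppressed")
  expect_equal(classify_response(al, 3, "Hit")$direction, "none")
  # closed-form t statistic oracle for the activated case
  time <- al$time
  x <- sapply(1:20, function(j) {
    mean(al$data[1, time >= 0, j]) - mean(al$data[1, time < 0, j])
  })
  p_oracle <- pt(mean(x) / (sd(x) / sqrt(20)), 19, lower.tail = FALSE)
  expect_equal(classify_response(al, 1, "Hit")$p_activated, p_oracle,
               tolerance = 1e-12)
  # all-zero responses -> none
  al0 <- toy_aligned(array(0, c(1, 80, 5)), al$time, rep("Hit", 5))
  expect_equal(classify_response(al0, 1, "Hit")$direction, "none")
  # fewer than 3 trials -> insufficient
  al2 <- planted_aligned(0.3, n_trials = 2)
  expect_equal(classify_response(al2, 1, "Hit")$direction, "insufficient")
})

test_that("classify_response type-I error matches the two-one-tailed budget", {
  set.seed(11)
  al <- null_aligned(400)
  dirs <- vapply(1:400, function(i) classify_response(al, i, "Hit")$direction,
                 character(1))
  expect_equal(mean(dirs != "none"), 0.10, tolerance = 0.04)
})

test_that("trial_activity implements the strict 2-SD peak criterion", {
  fs <- 20
  time <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  bi <- time < 0
  # hand-built: zero-SD baseline with a small peak -> active
  d <- array(0, c(2, length(time), 1))
  d[1, which(time >= 1)[1], 1] <- 0.1
  A <- trial_activity(toy_aligned(d, time, "Hit"))
  expect_equal(A[1, 1], 1L)   # sd 0, excess 0.1 > 0
  expect_equal(A[2, 1], 0L)   # flat everywhere -> inactive
  # peak excess exactly 2 SD -> inactive (strict inequality)
  set.seed(4)
  base <- rnorm(sum(bi), 0, 0.1)
  tr <- c(base, rep(0, sum(!bi)))
  sd_b <- sd(base); mu_b <- mean(base)
  tr[!bi] <- mu_b + 2 * sd_b   # constant response exactly at the threshold
  d2 <- array(tr, c(1, length(time), 1))
  expect_equal(trial_activity(toy_aligned(d2, time, "Hit"))[1, 1], 0L)
  # nudged above threshold -> active
  tr[!bi] <- mu_b + 2 * sd_b + 1e-6
  d3 <- array(tr, c(1, length(time), 1))
  expect_equal(trial_activity(toy_aligned(d3, time, "Hit"))[1, 1], 1L)
})

test_that("toy activity matrix reproduces hand-enumerated population statistics", {
  # 5 neurons x 4 trials; planted excesses {3,3,0,0,3} * SD on trial 1
  fs <- 20
  time <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  set.seed(5)
  d <- array(rnorm(5 * length(time) * 4, 0, 0.1), c(5, length(time), 4))
  plant <- rbind(c(1, 1, 0, 0, 1),   # trial 1 pattern
                 c(1, 0, 0, 0, 0),
                 c(0, 0, 0, 0, 0),
                 c(1, 1, 1, 1, 1))
  for (k in 1:4) for (i in 1:5) {
    if (plant[k, i]) d[i, time >= 0, k] <- d[i, time >= 0, k] + 1
  }
  A <- trial_activity(toy_aligned(d, time, c("Hit", "Hit", "FA", "FA")))
  expect_equal(unclass(A), t(plant), ignore_attr = TRUE)
  s <- synchronicity(A)
  expect_equal(as.numeric(s), colMeans(t(plant)))
  expect_equal(as.numeric(s[1]), 3 / 5)
  r <- reliability(A)
  expect_equal(r, rowMeans(t(plant)))
  # double-counting identity: sum over trials of (sync * n) equals
  # sum over neurons of (reliability * n_trials)
  expect_equal(sum(s * 5), sum(r * 4))
})

test_that("synchronicity and reliability hit their boundary values", {
  time <- seq(-2, 1.95, by = 0.05)
  d_on <- array(0, c(3, 80, 4)); d_on[, time >= 0, ] <- 1
  A_on <- trial_activity(toy_aligned(d_on, time, rep("Hit", 4)))
  expect_equal(as.numeric(synchronicity(A_on)), rep(1, 4))
  expect_equal(reliability(A_on, "Hit"), rep(1, 3))
  d_off <- array(0, c(3, 80, 4))
  A_off <- trial_activity(toy_aligned(d_off, time, rep("Hit", 4)))
  expect_equal(as.numeric(synchronicity(A_off)), rep(0, 4))
  expect_equal(reliability(A_off), rep(0, 3))
})

test_that("stability reports flat, decaying and degenerate cases", {
  # time-invariant generator: slope CI contains 0 (over seeds)
  covered <- 0
  for (s in 1:20) {
    set.seed(s)
    A <- matrix(rbinom(30 * 40, 1, 0.6), 30, 40)
    st <- stability(structure(A, trial_types = rep("Hit", 40)))
    if (st$slope_ci[1] <= 0 && 0 <= st$slope_ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 16)  # ~95% coverage
  # monotone decay in activation probability -> negative slope
  set.seed(1)
  p <- seq(0.9, 0.1, length.out = 40)
  Ad <- sapply(p, function(pp) rbinom(30, 1, pp))
  std <- stability(structure(Ad, trial_types = rep("Hit", 40)))
  expect_lt(std$slope, 0)
  expect_lt(std$p_value, 0.01)
  # single trial: undefined sentinel
  st1 <- stability(structure(matrix(1, 5, 1), trial_types = "Hit"))
  expect_true(is.na(st1$slope))
})

test_that("category_table forms exclusive categories that sum to n", {
  al <- planted_aligned(rep(0.4, 6), types = rep(c("Hit", "FA", "Miss", "CR"),
                                                 each = 5))
  res <- classify_all(al)
  ct <- category_table(res)
  expect_equal(sum(ct$counts[c("both", "reward_only", "punishment_only",
                               "none")]), 6)
  expect_equal(unname(ct$fractions["both"]), 1)
  expect_equal(unname(ct$fractions["all_types"]), 1)
  # zero responders
  al0 <- toy_aligned(array(0, c(4, 80, 20)), al$time,
                     rep(c("Hit", "FA", "Miss", "CR"), each = 5))
  ct0 <- category_table(classify_all(al0))
  expect_equal(unname(ct0$counts["none"]), 4)
  expect_equal(unname(ct0$counts["both"]), 0)
})

test_that("category recovery matches the planted responder mix", {
  ses <- cached_session("cat439", n_neurons = 250, n_trials = 96, seed = 8,
                        noise_sd = 0.05)
  al <- align_trials(ses, mode = "expected_reinforcement", window = c(-2, 4))
  ct <- category_table(classify_all(al))
  p_hat <- unname(ct$fractions["both"])
  ci <- stats::binom.test(round(p_hat * 250), 250, p = 0.73)$conf.int
  expect_true(ci[1] <= 0.73 && 0.73 <= ci[2])
})

test_that("amplitude correlation behaves at its fixed points and null", {
  hit <- c(1, 2, 3, 4, 5)
  expect_equal(amplitude_correlation(hit, 2 * hit), 1)
  expect_true(is.na(amplitude_correlation(hit, rep(1, 5))))
  # independent vectors: |R| < 2/sqrt(n) on average over seeds
  set.seed(6)
  rs <- replicate(50, amplitude_correlation(rnorm(100), rnorm(100)))
  expect_lt(mean(abs(rs)), 2 / sqrt(100))
})

test_that("cv_partition separates cell-to-cell from inter-individual variability", {
  expect_equal(cv_partition(rep(2, 10), rep(1:2, each = 5))$cell_to_cell, 0)
  # closed form: values {1, 3} -> CV = sqrt(2)/2
  cv13 <- cv_partition(c(1, 3, 1, 3), c(1, 1, 2, 2))
  expect_equal(cv13$per_session[[1]], sqrt(2) / 2, tolerance = 1e-12)
  # equal session means, positive within-session spread:
  # inter-individual CV shrinks with n while cell CV stays put
  set.seed(7)
  make <- function(n_per) {
    x <- unlist(lapply(1:6, function(s) rnorm(n_per, mean = 10, sd = 2)))
    cv_partition(x, rep(1:6, each = n_per))
  }
  small <- make(10); big <- make(2000)
  expect_lt(big$inter_individual, small$inter_individual + 0.02)
  expect_lt(big$inter_individual, 0.02)
  expect_equal(big$cell_to_cell, 0.2, tolerance = 0.02)
  expect_error(cv_partition(1:4, rep(1, 4)), "sessions")
})
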