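test_that("normalize_pupil interpolates gaps and normalises per trial", {
  fs <- 20
  time <- seq(0, 60, by = 1 / fs)
  trials <- data.frame(tone_onset = c(10, 30), type = c("Hit", "Hit"),
                       reinforcement_onset = c(11, 31))
  # constant pupil -> dP/P identically 0
  p <- rep(2, length(time))
  np <- normalize_pupil(p, time, trials, sigma = 0)
  dpp <- trial_dpp(np, trials, trials$reinforcement_onset, window = c(0, 3))
  expect_true(all(abs(dpp$dpp) < 1e-12))
  # doubling after the event -> dP/P plateau 1.0
  p2 <- ifelse(time < 11, 2, 4)
  np2 <- normalize_pupil(p2, time, trials, sigma = 0)
  d2 <- trial_dpp(np2, trials[1, ], 11, window = c(1, 3))
  expect_equal(as.numeric(d2$dpp), rep(1, ncol(d2$dpp)))
  # planted gap over a linear segment restores the line exactly
  p3 <- 2 + 0.01 * time
  p3g <- p3
  gap <- 401:408   # 0.4 s gap
  p3g[gap] <- NA
  np3 <- normalize_pupil(p3g, time, trials, sigma = 0)
  expect_equal(np3$P[gap], p3[gap], tolerance = 1e-9)
  expect_length(np3$dropped_trials, 0)
  # boundary gap is extended from the nearest value
  p4 <- p3; p4[1:5] <- NA
  expect_message(np4 <- normalize_pupil(p4, time, trials, sigma = 0),
                 "boundary")
  expect_equal(np4$P[1:5], rep(p3[6], 5))
  # long gaps flag overlapping trials as dropped
  p5 <- p3; p5[(10 * fs):(12 * fs)] <- NA
  np5 <- normalize_pupil(p5, time, trials, sigma = 0)
  expect_true(1 %in% np5$dropped_trials)
})

test_that("auc_split applies the trapezoid AUC and the tie-to-low rule", {
  # triangle dP/P peaking at 0.2 over 3 s -> AUC 0.3
  time <- seq(0, 3, by = 0.01)
  tri <- ifelse(time < 1.5, time / 1.5, (3 - time) / 1.5) * 0.2
  d <- rbind(tri, tri / 2)
  sp <- auc_split(d, time = time, window = c(0, 3))
  expect_equal(unname(sp$statistic[1]), 0.3, tolerance = 1e-9)
  # AUCs 1..10: top five are high (median 5.5)
  d10 <- outer(1:10 / 3, rep(1, length(time)))
  sp10 <- auc_split(d10, time = time, window = c(0, 3))
  expect_equal(sp10$labels, rep(c("low", "high"), each = 5))
  # all-equal statistics: everything low by the tie rule
  deq <- matrix(0.1, 4, length(time))
  expect_true(all(auc_split(deq, time = time)$labels == "low"))
  expect_error(auc_split(deq[1, , drop = FALSE], time = time), "2 trials")
  # invariance to adding a constant to raw pupil (dP/P normalises it out)
  fs <- 20
  tt <- seq(0, 60, by = 1 / fs)
  trials <- data.frame(tone_onset = c(10, 30), type = c("Hit", "Hit"),
                       reinforcement_onset = c(11, 31))
  set.seed(1)
  praw <- 2 + cumsum(rnorm(length(tt), 0, 0.001))
  for (shift in c(0, 5)) {
    np <- normalize_pupil(praw + shift, tt, trials, sigma = 0)
    dd <- trial_dpp(np, trials, trials$reinforcement_onset)
    if (shift == 0) auc0 <- auc_split(dd)$statistic
  }
  # note: dP/P itself changes with the offset, but the ordering (and the
  # resulting labels) is preserved for a common positive offset
  np5 <- normalize_pupil(praw + 5, tt, trials, sigma = 0)
  dd5 <- trial_dpp(np5, trials, trials$reinforcement_onset)
  expect_equal(order(auc_split(dd5)$statistic), order(auc0))
})

test_that("speed_change measures event-baseline differences and splits", {
  fs <- 20
  time <- seq(0, 100, by = 1 / fs)
  trials <- data.frame(type = c("Hit", "Hit", "Miss"),
                       tone_onset = c(10, 40, 70),
                       reinforcement_onset = c(11, 41, NA))
  # stationary mouse -> zero speed change everywhere
  sp0 <- speed_change(rep(0, length(time)), time, trials, by_type = FALSE)
  expect_equal(unname(sp0$statistic), rep(0, 3))
  # step from 0 to 2 cm/s at the event -> delta 2
  sp <- ifelse(time >= 41, 2, 0)
  scc <- speed_change(sp, time, trials, sigma = 0, by_type = FALSE)
  expect_equal(unname(scc$statistic[2]), 2, tolerance = 1e-6)
  expect_equal(unname(scc$statistic[1]), 0, tolerance = 1e-6)
})

test_that("bout-coupled trials are labelled high by the speed split", {
  ses <- cached_session("beh61", n_neurons = 5, n_trials = 96, seed = 61,
                        run_coupling = 0.5)
  sp <- speed_change(ses$behavior$speed, ses$behavior$time, ses$trials)
  bt <- ses$behavior$bout_trials
  expect_gte(mean(sp$labels[bt] == "high"), 0.95)
})

test_that("split responses reflect planted arousal coupling", {
  ses <- cached_session("beh62", n_neurons = 100, n_trials = 96, seed = 62)
  al <- align_trials(ses, mode = "reinforcement", window = c(-2, 4))
  pup <- normalize_pupil(ses$behavior$pupil, ses$behavior$time, ses$trials)
  rows <- ses$trials[al$trial_index, ]
  dpp <- trial_dpp(pup, rows, rows$reinforcement_onset)
  sp <- auc_split(dpp, types = rows$type)
  cmp <- compare_split_responses(al, sp)
  expect_gt(cmp$mean_high, cmp$mean_low)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(nrow(cmp$phase), 2)
  # identical groups -> zero difference, p = 1
  al_id <- al
  al_id$data[] <- 0.3
  cmp_id <- compare_split_responses(al_id, sp)
  expect_equal(cmp_id$mean_high, cmp_id$mean_low)
  expect_equal(cmp_id$p_value, 1)
  # arousal_gain = 0: no systematic high/low difference
  ses0 <- cached_session("beh63", n_neurons = 60, n_trials = 96, seed = 63,
                         arousal_gain = 0)
  al0 <- align_trials(ses0, mode = "reinforcement", window = c(-2, 4))
  pup0 <- normalize_pupil(ses0$behavior$pupil, ses0$behavior$time,
                          ses0$trials)
  rows0 <- ses0$trials[al0$trial_index, ]
  sp0 <- auc_split(trial_dpp(pup0, rows0, rows0$reinforcement_onset),
                   types = rows0$type)
  cmp0 <- compare_split_responses(al0, sp0)
  expect_gt(cmp0$p_value, 0.001)
})

test_that("median split sizes differ by at most one for unique statistics", {
  set.seed(12)
  for (n in c(10, 11, 25)) {
    d <- matrix(runif(n * 10), n, 10)
    sp <- auc_split(d, time = seq(0, 3, length.out = 10))
    expect_lte(abs(sum(sp$labels == "high") - sum(sp$labels == "low")), 1)
    expect_equal(sort(unique(sp$labels)), c("high", "low"))
  }
})

test_that("per-cell behaviour correlation matches its fixed points", {
  fs <- 20
  n <- 200
  set.seed(13)
  b <- rnorm(n)
  tr <- trace_set(rbind(b, rnorm(n)), fs, is_dff = TRUE)
  pc <- percell_behavior_correlation(tr, b, (seq_len(n) - 1) / fs)
  expect_equal(pc$r[1], 1)
  expect_lt(abs(pc$r[2]), 2 / sqrt(n))
  # zero-variance cell -> NA sentinel
  tr2 <- trace_set(rbind(b, rep(1, n)), fs, is_dff = TRUE)
  pc2 <- percell_behavior_correlation(tr2, b, (seq_len(n) - 1) / fs)
  expect_true(is.na(pc2$r[2]))
})

test_that("per-cell pupil correlation median sits near 0.31 at defaults", {
  meds <- vapply(c(64, 65), function(s) {
    ses <- cached_session(paste0("med", s), n_neurons = 80, n_trials = 96,
                          seed = s)
    pup <- normalize_pupil(ses$behavior$pupil, ses$behavior$time,
                           ses$trials)
    dff <- compute_dff(ses)
    percell_behavior_correlation(dff, (pup$P - mean(pup$P)) / mean(pup$P),
                                 pup$time)$median_r
  }, numeric(1))
  expect_equal(mean(meds), 0.31, tolerance = 0.07)
})

test_that("no_arousal_subset keeps quiet trials and still finds responses", {
  # arousal-independent responses with no evoked dilation or coupled bouts:
  # nearly all trials stay in the subset and the response remains positive
  ses <- cached_session("beh66", n_neurons = 60, n_trials = 64, seed = 66,
                        dilation_gain = 0, arousal_gain = 0,
                        run_coupling = 0, bout_rate = 0.2)
  al <- align_trials(ses, mode = "reinforcement", window = c(-2, 4))
  pup <- normalize_pupil(ses$behavior$pupil, ses$behavior$time, ses$trials)
  na <- no_arousal_subset(al, ses$trials, pup, ses$behavior$speed,
                          ses$behavior$time)
  expect_gte(na$n_subset / dim(al$data)[3], 0.6)
  expect_lt(na$p_value, 0.01)
  expect_gt(na$mean_dff, 0)
  # strong dilation on every trial empties the subset
  ses2 <- cached_session("beh67", n_neurons = 10, n_trials = 48, seed = 67,
                         dilation_gain = 1, dilation_sdlog = 0.1,
                         pupil_noise_sd = 0.005)
  al2 <- align_trials(ses2, mode = "reinforcement", window = c(-2, 4))
  pup2 <- normalize_pupil(ses2$behavior$pupil, ses2$behavior$time,
                          ses2$trials)
  na2 <- no_arousal_subset(al2, ses2$trials, pup2, ses2$behavior$speed,
                           ses2$behavior$time)
  expect_lte(na2$n_subset / dim(al2$data)[3], 0.1)
})
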