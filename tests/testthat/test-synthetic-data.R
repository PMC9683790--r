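test_that("archetype kernels are causal, normalised and correctly shaped", {
  t <- seq(0, 10, by = 0.02)
  for (nm in vip_archetypes()) {
    k <- archetype_kernel(nm, t)
    expect_true(all(k >= 0), info = nm)
    expect_equal(max(k), 1, info = nm)
  }
  expect_equal(archetype_kernel("fast", 0), 0)
  k_del <- archetype_kernel("delayed", t)
  expect_true(all(k_del[t <= 0.5] == 0))
  k_sus <- archetype_kernel("sustained", t)
  expect_equal(k_sus[which.max(k_sus)], 1)
  # biphasic second lobe peaks near 2 s
  k_bi <- archetype_kernel("biphasic", t)
  late <- t > 1.6
  expect_equal(t[late][which.max(k_bi[late])], 2, tolerance = 0.15)
  # slow kernel peaks later than fast
  expect_gt(which.max(archetype_kernel("slow", t)),
            which.max(archetype_kernel("fast", t)))
  expect_error(archetype_kernel("bogus", t), "fast")
})

test_that("generate_session respects counts, determinism and null settings", {
  cfg <- session_config(n_neurons = 10, n_trials = 128, seed = 1)
  ses <- generate_session(cfg)
  expect_equal(nrow(ses$trials), 128)
  expect_true(all(diff(ses$trials$tone_onset) > 0))
  expect_true(all(is.finite(ses$traces)))
  expect_length(ses$truth$archetype, 10)
  # Hit/FA reinforcement = first lick + delay; Miss/CR none
  reinforced <- ses$trials$type %in% c("Hit", "FA")
  expect_equal(ses$trials$reinforcement_onset[reinforced],
               ses$trials$first_lick[reinforced] + 0.5)
  expect_true(all(is.na(ses$trials$reinforcement_onset[!reinforced])))
  # same config, same seed: identical output
  ses2 <- generate_session(cfg)
  expect_identical(ses, ses2)
  # different seed differs
  ses3 <- generate_session(session_config(n_neurons = 10, n_trials = 128,
                                          seed = 2))
  expect_false(identical(ses$traces, ses3$traces))
  # zero noise + zero gain: per-neuron traces constant at F0
  cfg0 <- session_config(n_neurons = 4, n_trials = 16, seed = 1,
                         noise_sd = 0, response_gain = 0, cue_gain = 0,
                         p_cue = 0)
  ses0 <- generate_session(cfg0)
  expect_equal(apply(ses0$traces, 1, stats::sd), rep(0, 4))
  expect_equal(ses0$traces[, 1], ses0$truth$f0)
})

test_that("trial-type frequencies converge to configured probabilities", {
  cfg <- session_config(n_neurons = 1, n_trials = 10000, seed = 42,
                        p_go = 0.6, p_lick_go = 0.8, p_lick_nogo = 0.25)
  ses <- generate_session(cfg)
  go <- ses$trials$type %in% c("Hit", "Miss")
  ci <- stats::binom.test(sum(go), 10000, p = 0.6)$conf.int
  expect_true(ci[1] <= 0.6 && 0.6 <= ci[2])
  hit_given_go <- mean(ses$trials$type[go] == "Hit")
  ci2 <- stats::binom.test(sum(ses$trials$type[go] == "Hit"), sum(go),
                           p = 0.8)$conf.int
  expect_true(ci2[1] <= 0.8 && 0.8 <= ci2[2])
  # reaction times live in the truncation interval
  rt <- ses$trials$reaction_time
  expect_true(all(rt[!is.na(rt)] >= 0.1 & rt[!is.na(rt)] <= 1.5))
})

test_that("planted archetype mean response matches its kernel over many trials", {
  # one neuron per archetype, many trials, average out the noise
  cfg <- session_config(n_neurons = 25, n_trials = 400, p_go = 1,
                        p_lick_go = 1, seed = 7, arousal_gain = 0,
                        p_cue = 0, iti_range = c(18, 20),
                        gain_shared_sdlog = 0, gain_private_sdlog = 0,
                        response_probs = c(both = 1, reward_only = 0,
                                           punishment_only = 0, none = 0))
  ses <- generate_session(cfg)
  al <- align_trials(ses, mode = "reinforcement", window = c(0, 6))
  mean_resp <- apply(al$data, c(1, 2), mean)
  for (i in 1:25) {
    kern <- archetype_kernel(ses$truth$archetype[i], al$time)
    expect_gt(stats::cor(mean_resp[i, ], kern), 0.99)
  }
})

test_that("generate_behavior: baseline mean, determinism, missing samples", {
  cfg <- session_config(n_neurons = 1, n_trials = 8, seed = 5,
                        blink_rate = 0)
  # no trials: baseline-only pupil; long-run mean within 2% of baseline
  empty <- data.frame()
  beh0 <- generate_behavior(empty, cfg, duration = 600)
  expect_equal(mean(beh0$pupil), cfg$pupil_baseline, tolerance = 0.02)
  expect_true(all(beh0$pupil > 0))
  # determinism
  ses <- generate_session(cfg)
  beh1 <- generate_behavior(ses$trials, cfg)
  beh2 <- generate_behavior(ses$trials, cfg)
  expect_identical(beh1, beh2)
  expect_identical(beh1$pupil, ses$behavior$pupil)
  # blink gaps appear as NA when enabled
  cfgb <- session_config(n_neurons = 1, n_trials = 8, seed = 5,
                         blink_rate = 20)
  behb <- generate_behavior(ses$trials, cfgb)
  expect_true(anyNA(behb$pupil))
  expect_equal(length(behb$time), length(behb$pupil))
  expect_equal(length(behb$time), length(behb$speed))
})

test_that("pupil is event-locked only when dilation gain is positive", {
  # with zero dilation gain the per-trial mean pupil is statistically
  # identical before and after reinforcement (per-trial means are used so
  # the KS samples are approximately independent)
  for (s in c(9, 10)) {
    cfg0 <- session_config(n_neurons = 1, n_trials = 60, seed = s,
                           dilation_gain = 0, blink_rate = 0)
    ses0 <- generate_session(cfg0)
    beh <- ses0$behavior
    reinf <- ses0$trials$reinforcement_onset
    reinf <- reinf[!is.na(reinf)]
    pre <- vapply(reinf, function(ev) {
      mean(beh$pupil[beh$time >= ev - 2 & beh$time < ev])
    }, numeric(1))
    post <- vapply(reinf, function(ev) {
      mean(beh$pupil[beh$time >= ev & beh$time < ev + 2])
    }, numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(pre, post)$p.value), 0.01)
  }
  # with the default dilation gain the post-event pupil is clearly larger
  cfg1 <- session_config(n_neurons = 1, n_trials = 60, seed = 9,
                         blink_rate = 0)
  ses1 <- generate_session(cfg1)
  beh1 <- ses1$behavior
  reinf <- ses1$trials$reinforcement_onset
  reinf <- reinf[!is.na(reinf)]
  pre <- vapply(reinf, function(ev) {
    mean(beh1$pupil[beh1$time >= ev - 2 & beh1$time < ev])
  }, numeric(1))
  post <- vapply(reinf, function(ev) {
    mean(beh1$pupil[beh1$time >= ev & beh1$time < ev + 2])
  }, numeric(1))
  expect_lt(suppressWarnings(stats::ks.test(pre, post)$p.value), 0.01)
  expect_gt(mean(post - pre), 0)
})

test_that("tile stacks translate the template scene as requested", {
  # zero shift, zero noise: frames identical to template
  st0 <- generate_tile_stack(2, 3, shifts = matrix(0, 3, 2), noise_sd = 0,
                             seed = 1)
  for (f in 1:3) {
    expect_equal(st0$tiles[[1]][, , f], st0$templates[[1]])
  }
  # integer shift: brute-force 2-D correlation oracle finds the shift
  st <- generate_tile_stack(1, 2, shifts = rbind(c(0, 0), c(3, -2)),
                            noise_sd = 0, seed = 2)
  tm <- st$templates[[1]]
  mv <- st$tiles[[1]][, , 2]
  n <- nrow(tm)
  best <- c(NA, NA); bc <- -Inf
  for (dx in -4:4) for (dy in -4:4) {
    rs <- max(1, 1 + dy):min(n, n + dy)
    cs <- max(1, 1 + dx):min(n, n + dx)
    cc <- stats::cor(as.vector(tm[rs, cs]), as.vector(mv[rs - dy, cs - dx]))
    if (cc > bc) { bc <- cc; best <- c(dx, dy) }
  }
  expect_equal(best, c(3, -2))
  expect_gt(bc, 0.9999)
  # determinism and margin guard
  st2 <- generate_tile_stack(1, 2, shifts = rbind(c(0, 0), c(3, -2)),
                             noise_sd = 0, seed = 2)
  expect_identical(st$tiles, st2$tiles)
  expect_error(generate_tile_stack(1, 1, shifts = c(99, 0), seed = 1),
               "margin")
})
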