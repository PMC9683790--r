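#' Configuration for a synthetic go/no-go imaging session
#'
#' Bundles and validates every knob of the synthetic session generator.  The
#' defaults describe a typical early-training session: 128 trials, half go
#' tones, lick probabilities that yield all four outcomes (Hit, FA, Miss,
#' CR), a 0.5 s delay between the triggering lick and reinforcement
#' delivery, GCaMP6f-like response kinetics through the five temporal
#' archetypes, arousal-coupled response gain, and a bimodal soma-diameter
#' population.
#'
#' @param n_neurons Number of simultaneously recorded neurons.
#' @param n_trials Number of trials (>= 4).
#' @param p_go Probability that a trial is a go trial.
#' @param p_lick_go,p_lick_nogo Probability of licking on go / no-go trials.
#' @param sample_rate Imaging sample rate (Hz).
#' @param reinforcement_delay Delay between first lick and reinforcement (s).
#' @param reaction_time_mean,reaction_time_sd Log-normal reaction-time
#'   parameters (s); draws truncated to \[0.1, 1.5\] s.
#' @param archetype_mix Named non-negative weights over the five archetypes,
#'   summing to 1 (see [vip_archetypes()]).
#' @param response_gain Mean reinforcement response amplitude (dF/F).
#' @param noise_sd Gaussian trace noise (dF/F units).
#' @param arousal_gain Dimensionless coupling of the trial's pupil change
#'   (dP/P) to response amplitude.
#' @param seed Integer seed; every generator draw is deterministic given it.
#' @param response_probs Named probabilities over responder categories
#'   `both`, `reward_only`, `punishment_only`, `none` (must sum to 1).
#' @param p_cue Probability that a neuron also responds to the auditory cue.
#' @param cue_gain Mean cue response amplitude (dF/F).
#' @param gain_shared_sdlog,gain_private_sdlog Log-normal spread of the
#'   per-neuron gain shared between reward and punishment, and of the
#'   reinforcer-private gain.  The defaults place the population Pearson
#'   correlation of reward vs punishment amplitudes at 0.73.
#' @param soma_means,soma_sd,soma_weights Two-component Gaussian mixture for
#'   soma diameters (um).
#' @param pupil_baseline Pupil baseline diameter (a.u.).
#' @param dilation_gain Median reinforcement-evoked pupil dilation (dP/P).
#' @param dilation_sdlog Log-normal spread of per-trial dilation amplitudes;
#'   together with `dilation_gain` and `arousal_gain` the defaults place the
#'   high/low arousal-split group dilations near 0.18 and 0.04 dP/P with a
#'   high/low response ratio near 1.5.
#' @param pupil_noise_sd Stationary s.d. of the mean-reverting pupil
#'   baseline process (a.u.).
#' @param blink_rate Blink rate (per minute); blinks insert missing samples.
#' @param bout_rate Spontaneous locomotion bout rate (per minute).
#' @param run_coupling Probability that a reinforced trial triggers a bout.
#' @param f0_range Range of per-neuron raw fluorescence baselines (a.u.).
#' @param iti_range Range of inter-trial intervals (s), drawn uniformly.
#' @param area_label Cortical area label stamped on every trial.
#' @param on_missing_type What to do when a drawn session lacks one of the
#'   four trial types: `"regenerate"` (redraw outcomes), `"error"`, or
#'   `"ignore"`.
#' @return An object of class `vip_config` (a validated list).
#' @export
session_config <- function(n_neurons = 100, n_trials = 128, p_go = 0.5,
                           p_lick_go = 0.8, p_lick_nogo = 0.3,
                           sample_rate = 20, reinforcement_delay = 0.5,
                           reaction_time_mean = 0.5, reaction_time_sd = 0.2,
                           archetype_mix = c(fast = 109, delayed = 88,
                                             sustained = 177, biphasic = 120,
                                             slow = 112) / 606,
                           response_gain = 0.3, noise_sd = 0.15,
                           arousal_gain = 4, seed = 1,
                           response_probs = c(both = 0.73, reward_only = 0.10,
                                              punishment_only = 0.12,
                                              none = 0.05),
                           p_cue = 0.15, cue_gain = 0.08,
                           gain_shared_sdlog = 0.40,
                           gain_private_sdlog = 0.231,
                           soma_means = c(8, 11), soma_sd = 0.8,
                           soma_weights = c(0.5, 0.5),
                           pupil_baseline = 1, dilation_gain = 0.08,
                           dilation_sdlog = 1, pupil_noise_sd = 0.02,
                           blink_rate = 1,
                           bout_rate = 2, run_coupling = 0.3,
                           f0_range = c(80, 120), iti_range = c(9, 11),
                           area_label = "MPta",
                           on_missing_type = c("regenerate", "error",
                                               "ignore")) {
  probs <- c(p_go, p_lick_go, p_lick_nogo, p_cue, run_coupling)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_trials < 4) stop("n_trials must be >= 4")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (length(archetype_mix) != 5 || any(archetype_mix < 0) ||
      abs(sum(archetype_mix) - 1) > 1e-9) {
    stop("archetype_mix must be 5 non-negative weights summing to 1")
  }
  if (is.null(names(archetype_mix))) names(archetype_mix) <- vip_archetypes()
  if (abs(sum(response_probs) - 1) > 1e-9 || any(response_probs < 0)) {
    stop("response_probs must be non-negative and sum to 1")
  }
  cfg <- list(n_neurons = n_neurons, n_trials = n_trials, p_go = p_go,
              p_lick_go = p_lick_go, p_lick_nogo = p_lick_nogo,
              sample_rate = sample_rate,
              reinforcement_delay = reinforcement_delay,
              reaction_time_mean = reaction_time_mean,
              reaction_time_sd = reaction_time_sd,
              archetype_mix = archetype_mix, response_gain = response_gain,
              noise_sd = noise_sd, arousal_gain = arousal_gain,
              seed = as.integer(seed), response_probs = response_probs,
              p_cue = p_cue, cue_gain = cue_gain,
              gain_shared_sdlog = gain_shared_sdlog,
              gain_private_sdlog = gain_private_sdlog,
              soma_means = soma_means, soma_sd = soma_sd,
              soma_weights = soma_weights, pupil_baseline = pupil_baseline,
              dilation_gain = dilation_gain, dilation_sdlog = dilation_sdlog,
              pupil_noise_sd = pupil_noise_sd,
              blink_rate = blink_rate, bout_rate = bout_rate,
              run_coupling = run_coupling, f0_range = f0_range,
              iti_range = iti_range, area_label = area_label,
              on_missing_type = match.arg(on_missing_type))
  class(cfg) <- "vip_config"
  cfg
}

#' Generate a synthetic go/no-go imaging session
#'
#' Draws a full session: trial outcomes and timing, per-neuron ground truth
#' (archetype, responder category, gains, soma diameter), behaviour traces
#' (pupil, running speed, licks) and raw fluorescence traces.  Each
#' responsive neuron's trace is `F0 * (1 + dF/F signal + noise)`, where the
#' signal is its archetype kernel placed at reinforcement onsets (and
#' optionally cue onsets), with amplitude scaled by
#' `(1 + arousal_gain * dP/P)` of the trial.  Byte-identical output is
#' guaranteed for a fixed configuration (including its seed).
#'
#' @param config A [session_config()] object.
#' @return An object of class `vip_session`: a list with elements `trials`
#'   (data frame: `index`, `type`, `tone_onset`, `first_lick`,
#'   `reaction_time`, `reinforcement_onset`, `n_licks`, `area_label`,
#'   `session_id`), `traces` (neurons x samples raw fluorescence), `time`,
#'   `sample_rate`, `behavior` (see [generate_behavior()]), `truth`
#'   (per-neuron ground truth), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "vip_config"))
  with_seed(config$seed, {
    trials <- draw_trials(config)
    behavior <- generate_behavior(trials, config)
    n <- config$n_neurons
    fs <- config$sample_rate
    time <- behavior$time

    archetype <- sample(names(config$archetype_mix), n, replace = TRUE,
                        prob = config$archetype_mix)
    category <- sample(names(config$response_probs), n, replace = TRUE,
                       prob = config$response_probs)
    responds_reward <- category %in% c("both", "reward_only")
    responds_punishment <- category %in% c("both", "punishment_only")
    responds_cue <- stats::runif(n) < config$p_cue
    comp <- sample(seq_along(config$soma_means), n, replace = TRUE,
                   prob = config$soma_weights)
    soma <- stats::rnorm(n, config$soma_means[comp], config$soma_sd)
    g_shared <- stats::rlnorm(n, 0, config$gain_shared_sdlog)
    reward_gain <- config$response_gain * g_shared *
      stats::rlnorm(n, 0, config$gain_private_sdlog)
    punish_gain <- config$response_gain * g_shared *
      stats::rlnorm(n, 0, config$gain_private_sdlog)
    f0 <- stats::runif(n, config$f0_range[1], config$f0_range[2])

    dpp <- behavior$trial_dilation / config$pupil_baseline
    mult <- 1 + config$arousal_gain * dpp

    # kernels are evaluated at the exact (fractional-sample) event offset
    # and scaled by the continuous-time peak, so planted events carry no
    # sample-quantisation jitter
    peaks <- archetype_peak()
    klen <- 12L * as.integer(ceiling(fs))
    nsamp <- length(time)
    traces <- matrix(0, n, nsamp)
    reinf <- trials$reinforcement_onset
    is_hit <- trials$type == "Hit"
    is_fa <- trials$type == "FA"
    for (i in seq_len(n)) {
      y <- numeric(nsamp)
      lbl <- archetype[i]
      add_ev <- function(y, t_ev, amp) {
        i0 <- floor(t_ev * fs) + 1L
        idx <- i0:min(i0 + klen, nsamp)
        ts <- (idx - 1) / fs - t_ev
        y[idx] <- y[idx] + (amp / peaks[lbl]) * archetype_raw(lbl, ts)
        y
      }
      if (responds_reward[i]) {
        for (j in which(is_hit)) y <- add_ev(y, reinf[j],
                                             reward_gain[i] * mult[j])
      }
      if (responds_punishment[i]) {
        for (j in which(is_fa)) y <- add_ev(y, reinf[j],
                                            punish_gain[i] * mult[j])
      }
      if (responds_cue[i]) {
        for (j in seq_len(nrow(trials))) y <- add_ev(y, trials$tone_onset[j],
                                                     config$cue_gain)
      }
      traces[i, ] <- f0[i] * (1 + y + stats::rnorm(nsamp, 0, config$noise_sd))
    }

    truth <- list(archetype = archetype, category = category,
                  responds_reward = responds_reward,
                  responds_punishment = responds_punishment,
                  responds_cue = responds_cue, soma_diameter = soma,
                  reward_gain = reward_gain, punish_gain = punish_gain,
                  f0 = f0, trial_dpp = dpp, seed = config$seed)
    structure(list(trials = trials, traces = traces, time = time,
                   sample_rate = fs, behavior = behavior, truth = truth,
                   config = config),
              class = "vip_session")
  })
}

# Draw trial outcomes, timing and licks.
draw_trials <- function(config) {
  nt <- config$n_trials
  for (attempt in 1:200) {
    go <- stats::runif(nt) < config$p_go
    lick <- ifelse(go, stats::runif(nt) < config$p_lick_go,
                   stats::runif(nt) < config$p_lick_nogo)
    type <- ifelse(go, ifelse(lick, "Hit", "Miss"),
                   ifelse(lick, "FA", "CR"))
    if (all(c("Hit", "FA", "Miss", "CR") %in% type)) break
    if (config$on_missing_type == "error") {
      stop("drawn session lacks a trial type; set on_missing_type = ",
           "'regenerate' to redraw", call. = FALSE)
    }
    if (config$on_missing_type == "ignore") break
  }
  iti <- stats::runif(nt, config$iti_range[1], config$iti_range[2])
  tone <- 5 + cumsum(iti) - iti[1]
  m <- config$reaction_time_mean; s <- config$reaction_time_sd
  sdlog <- sqrt(log(1 + s^2 / m^2))
  mulog <- log(m) - sdlog^2 / 2
  rt <- stats::rlnorm(nt, mulog, sdlog)
  rt <- pmin(pmax(rt, 0.1), 1.5)
  rt[!lick] <- NA_real_
  first_lick <- tone + rt
  reinf <- ifelse(type %in% c("Hit", "FA"),
                  first_lick + config$reinforcement_delay, NA_real_)
  n_licks <- integer(nt)
  lick_times <- vector("list", nt)
  for (j in seq_len(nt)) {
    if (!lick[j]) next
    dur <- if (type[j] == "Hit") 2.5 else 0.4
    tt <- first_lick[j]
    while (tail(tt, 1) < first_lick[j] + dur) {
      tt <- c(tt, tail(tt, 1) + 0.13 + stats::rexp(1, 1 / 0.05))
    }
    lick_times[[j]] <- tt
    n_licks[j] <- length(tt)
  }
  trials <- data.frame(index = seq_len(nt), type = type, tone_onset = tone,
                       first_lick = first_lick, reaction_time = rt,
                       reinforcement_onset = reinf, n_licks = n_licks,
                       area_label = config$area_label,
                       session_id = sprintf("synth-%06d", config$seed),
                       stringsAsFactors = FALSE)
  attr(trials, "lick_times") <- lick_times
  attr(trials, "duration") <- max(tone) + 10
  trials
}

#' Generate pupil, running-speed and lick traces for a trial table
#'
#' The pupil is a slow mean-reverting baseline plus an event-evoked dilation
#' kernel (peaking about 1 s after reinforcement; a smaller dilation follows
#' the cue on unreinforced trials) plus noise, with blink gaps inserted as
#' `NA` runs.  Running speed is a sparse sequence of smooth bouts, some of
#' them coupled to reinforced trials.  Deterministic given the
#' configuration seed.
#'
#' @param trials A trial table as produced inside [generate_session()] (may
#'   have zero rows).
#' @param config A [session_config()].
#' @param duration Recording length (s); defaults to the span implied by
#'   `trials` or 60 s for an empty table.
#' @return Object of class `vip_behavior`: `time` (s), `pupil` (a.u., with
#'   `NA` blink gaps), `speed` (cm/s), `lick_raster` (0/1), plus per-trial
#'   ground truth `trial_dilation` (a.u.) and `bout_trials` (logical).
#' @export
generate_behavior <- function(trials, config, duration = NULL) {
  stopifnot(inherits(config, "vip_config"))
  duration <- duration %||% attr(trials, "duration") %||%
    if (nrow(trials)) max(trials$tone_onset) + 10 else 60
  fs <- config$sample_rate
  with_seed(config$seed + 1L, {
    time <- seq(0, duration, by = 1 / fs)
    nsamp <- length(time)
    dt <- 1 / fs

    # mean-reverting (AR(1)/OU) pupil baseline around pupil_baseline
    theta <- 0.1
    sig <- config$pupil_noise_sd * sqrt(2 * theta)
    p <- numeric(nsamp)
    p[1] <- config$pupil_baseline
    eps <- stats::rnorm(nsamp, 0, sig * sqrt(dt))
    for (i in 2:nsamp) {
      p[i] <- p[i - 1] + theta * (config$pupil_baseline - p[i - 1]) * dt +
        eps[i]
    }

    nt <- nrow(trials)
    dil_amp <- numeric(nt)
    kt <- seq(0, 12, by = dt)
    dil_kernel <- dexp_kernel(kt, 0.5, 2)
    if (max(dil_kernel) > 0) dil_kernel <- dil_kernel / max(dil_kernel)
    add_at <- function(x, t_ev, amp, kern) {
      i0 <- floor(t_ev * fs) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, nsamp)
      x[idx] <- x[idx] + amp * kern[seq_along(idx)]
      x
    }
    if (nt) {
      reinforced <- trials$type %in% c("Hit", "FA")
      dil_amp <- config$dilation_gain * config$pupil_baseline *
        stats::rlnorm(nt, 0, config$dilation_sdlog)
      for (j in seq_len(nt)) {
        if (reinforced[j]) {
          p <- add_at(p, trials$reinforcement_onset[j], dil_amp[j], dil_kernel)
        } else {
          dil_amp[j] <- 0.3 * dil_amp[j]
          p <- add_at(p, trials$tone_onset[j], dil_amp[j], dil_kernel)
        }
      }
    }

    # locomotion: spontaneous bouts plus trial-coupled bouts
    speed <- numeric(nsamp)
    bout_kernel <- function(dur_s) {
      bl <- max(2L, round(dur_s * fs))
      smooth_gaussian(c(rep(0, round(fs / 2)), rep(1, bl), rep(0, round(fs / 2))),
                      sigma = 0.15, sample_rate = fs)
    }
    n_spont <- stats::rpois(1, config$bout_rate * duration / 60)
    bout_starts <- stats::runif(n_spont, 0, max(duration - 5, 1))
    bout_trials <- logical(nt)
    if (nt) {
      reinforced <- trials$type %in% c("Hit", "FA")
      bout_trials <- reinforced & stats::runif(nt) < config$run_coupling
      bout_starts <- c(bout_starts, trials$reinforcement_onset[bout_trials])
    }
    for (b in bout_starts) {
      k <- bout_kernel(1 + stats::rexp(1, 1 / 2)) * (5 + stats::runif(1, 0, 10))
      speed <- add_at(speed, max(b - 0.5, 0), 1, k)
    }
    speed <- abs(speed + stats::rnorm(nsamp, 0, 0.05))

    # blink gaps (missing pupil samples)
    n_blinks <- stats::rpois(1, config$blink_rate * duration / 60)
    if (n_blinks > 0) {
      for (b in stats::runif(n_blinks, 1, duration - 1)) {
        i0 <- floor(b * fs) + 1L
        p[i0:min(i0 + round(0.2 * fs), nsamp)] <- NA_real_
      }
    }

    lick_raster <- numeric(nsamp)
    lt <- unlist(attr(trials, "lick_times"))
    lt <- lt[lt <= duration]
    if (length(lt)) lick_raster[floor(lt * fs) + 1L] <- 1

    structure(list(time = time, pupil = p, speed = speed,
                   lick_raster = lick_raster, trial_dilation = dil_amp,
                   bout_trials = bout_trials, sample_rate = fs),
              class = "vip_behavior")
  })
}

#' @method print vip_session
#' @export
print.vip_session <- function(x, ...) {
  cat("<vip_session> ", nrow(x$traces), " neurons, ", nrow(x$trials),
      " trials, ", round(max(x$time) / 60, 1), " min @ ", x$sample_rate,
      " Hz\n", sep = "")
  print(table(x$trials$type))
  invisible(x)
}
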