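#' Normalise a pupil trace
#'
#' Blink gaps (`NA` runs) no longer than `max_gap` seconds are linearly
#' interpolated; gaps touching the trace boundary are filled by
#' nearest-value extension; trials overlapping longer gaps are flagged as
#' dropped.  The trace is then Gaussian smoothed and a per-trial baseline
#' `P0` (mean over `baseline_window` before tone onset) is computed, giving
#' dP/P per trial via `(P - P0) / P0`.
#'
#' @param pupil Pupil diameter vector (a.u.), `NA` marking missing samples.
#' @param time Time axis (s), regular.
#' @param trials Trial table with `tone_onset` (may be empty).
#' @param sigma Gaussian smoothing SD (s; default 0.1).
#' @param max_gap Longest interpolatable gap (s).
#' @param baseline_window Window (s) relative to tone for `P0`.
#' @return Object of class `vip_pupil`: `P` (gap-free, smoothed), `time`,
#'   `P0` (per trial), `dropped_trials` (indices overlapping long gaps),
#'   `sample_rate`.
#' @export
normalize_pupil <- function(pupil, time, trials, sigma = 0.1,
                            max_gap = 0.5, baseline_window = c(-2, 0)) {
  fs <- 1 / stats::median(diff(time))
  n <- length(pupil)
  long_gap <- rep(FALSE, n)
  if (anyNA(pupil)) {
    r <- rle(is.na(pupil))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      gi <- starts[g]:ends[g]
      if (starts[g] == 1L || ends[g] == n) {
        # boundary gap: nearest-value extension
        fill <- if (starts[g] == 1L) pupil[ends[g] + 1L] else
          pupil[starts[g] - 1L]
        pupil[gi] <- fill
        message("boundary blink gap filled by nearest value")
      } else if (r$lengths[g] / fs <= max_gap) {
        pupil[gi] <- stats::approx(c(starts[g] - 1L, ends[g] + 1L),
                                   pupil[c(starts[g] - 1L, ends[g] + 1L)],
                                   xout = gi)$y
      } else {
        long_gap[gi] <- TRUE
      }
    }
    if (anyNA(pupil[!long_gap])) {
      pupil <- stats::approx(time[!is.na(pupil)], pupil[!is.na(pupil)],
                             xout = time, rule = 2)$y
    } else if (any(long_gap)) {
      # interpolate long gaps too, but remember which trials they touch
      pupil <- stats::approx(time[!is.na(pupil)], pupil[!is.na(pupil)],
                             xout = time, rule = 2)$y
    }
  }
  P <- smooth_gaussian(pupil, sigma, sample_rate = fs)
  nt <- if (is.null(trials)) 0L else nrow(trials)
  P0 <- numeric(nt); dropped <- integer(0)
  for (j in seq_len(nt)) {
    bi <- which(time >= trials$tone_onset[j] + baseline_window[1] &
                  time < trials$tone_onset[j] + baseline_window[2])
    P0[j] <- mean(P[bi])
    span <- which(time >= trials$tone_onset[j] + baseline_window[1] &
                    time <= trials$tone_onset[j] + 5)
    if (any(long_gap[span])) dropped <- c(dropped, j)
  }
  structure(list(P = P, time = time, P0 = P0, dropped_trials = dropped,
                 sample_rate = fs), class = "vip_pupil")
}

#' Per-trial dP/P segments
#'
#' @param pupil A [normalize_pupil()] result.
#' @param trials Trial table.
#' @param event Per-trial event times (s) the window is taken around
#'   (e.g. reinforcement onset, or tone onset for unreinforced trials).
#' @param window Window (s) relative to `event`.
#' @return List: `dpp` (trials x samples matrix of `(P - P0)/P0`), `time`
#'   (relative).
#' @export
trial_dpp <- function(pupil, trials, event, window = c(-2, 5)) {
  stopifnot(inherits(pupil, "vip_pupil"))
  fs <- pupil$sample_rate
  rel <- (ceiling(window[1] * fs):(ceiling(window[1] * fs) +
            round(diff(window) * fs) - 1L)) / fs
  out <- matrix(NA_real_, nrow(trials), length(rel))
  for (j in seq_len(nrow(trials))) {
    if (is.na(event[j])) next
    pos <- (event[j] + rel) * fs + 1
    seg <- interp_rows(matrix(pupil$P, 1), pos)[1, ]
    if (pupil$P0[j] <= 0) stop("non-positive pupil baseline at trial ", j)
    out[j, ] <- (seg - pupil$P0[j]) / pupil$P0[j]
  }
  list(dpp = out, time = rel)
}

# Median split helper: high iff statistic > median, ties (and values equal
# to the median) assigned to low.  Split within outcome type when given.
median_split <- function(stat, types = NULL) {
  lab <- rep(NA_character_, length(stat))
  groups <- if (is.null(types)) list(seq_along(stat)) else
    split(seq_along(stat), types)
  for (g in groups) {
    if (!length(g)) next
    med <- stats::median(stat[g])
    lab[g] <- ifelse(stat[g] > med, "high", "low")
  }
  lab
}

#' Arousal split by pupil-dilation area under the curve
#'
#' The trapezoidal area under the dP/P curve over `window` (default 0-3 s
#' after reinforcement) is computed per trial; trials above their outcome's
#' median are labelled `"high"`, the rest (including ties at the median)
#' `"low"`.
#'
#' @param dpp A [trial_dpp()] result (or a trials x samples matrix with a
#'   relative time attribute via `time`).
#' @param time Relative time axis when `dpp` is a plain matrix.
#' @param window Integration window (s).
#' @param types Optional per-trial outcome labels; the split is taken
#'   within each outcome.
#' @return Object of class `vip_split`: `labels` (`"high"`/`"low"`),
#'   `statistic` (AUC per trial), `median` (per group).
#' @export
auc_split <- function(dpp, time = NULL, window = c(0, 3), types = NULL) {
  if (is.list(dpp) && !is.null(dpp$dpp)) {
    time <- dpp$time; dpp <- dpp$dpp
  }
  stopifnot(!is.null(time))
  if (nrow(dpp) < 2) stop("auc_split needs at least 2 trials")
  wi <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  auc <- apply(dpp[, wi, drop = FALSE], 1, function(y) trapz(time[wi], y))
  labels <- median_split(auc, types)
  structure(list(labels = labels, statistic = auc,
                 statistic_name = "pupil_auc"), class = "vip_split")
}

#' Locomotion split by running-speed change
#'
#' Per trial, the change in Gauss-filtered absolute running speed between
#' the event window (0-2 s after reinforcement for Hit/FA, after tone for
#' Miss/CR) and the baseline window (-2-0 s before tone), followed by a
#' median split as in [auc_split()].
#'
#' @param speed Running-speed trace (cm/s).
#' @param time Time axis (s).
#' @param trials Trial table (`type`, `tone_onset`, `reinforcement_onset`).
#' @param sigma Gaussian filter SD (s).
#' @param event_window,baseline_window Windows (s).
#' @param by_type Split within outcome type (default `TRUE`).
#' @return A `vip_split` with `statistic` = speed change (cm/s) per trial.
#' @export
speed_change <- function(speed, time, trials, sigma = 0.1,
                         event_window = c(0, 2), baseline_window = c(-2, 0),
                         by_type = TRUE) {
  if (nrow(trials) < 2) stop("speed_change needs at least 2 trials")
  fs <- 1 / stats::median(diff(time))
  sp <- smooth_gaussian(abs(speed), sigma, sample_rate = fs)
  reinforced <- trials$type %in% c("Hit", "FA")
  event <- ifelse(reinforced, trials$reinforcement_onset, trials$tone_onset)
  delta <- vapply(seq_len(nrow(trials)), function(j) {
    ei <- which(time >= event[j] + event_window[1] &
                  time < event[j] + event_window[2])
    bi <- which(time >= trials$tone_onset[j] + baseline_window[1] &
                  time < trials$tone_onset[j] + baseline_window[2])
    mean(sp[ei]) - mean(sp[bi])
  }, numeric(1))
  labels <- median_split(delta, if (by_type) trials$type else NULL)
  structure(list(labels = labels, statistic = delta,
                 statistic_name = "speed_change"), class = "vip_split")
}

#' Compare neural responses between split groups
#'
#' Per-neuron mean dF/F over the response window in the high and low
#' groups, compared with a paired t-test across neurons, plus an
#' initial-phase (0-1 s) and late-phase (2-3 s) breakdown.
#'
#' @param aligned A [align_trials()] result whose trials match the split.
#' @param split A `vip_split` (labels per aligned trial).
#' @param response_window Window (s) for the main comparison.
#' @param phases Named list of extra windows.
#' @return List: `mean_high`, `mean_low` (population means, dF/F), `sem_high`,
#'   `sem_low`, `p_value` (paired t-test across neurons), `phase` (data
#'   frame per phase), `per_neuron` (matrix neurons x {high, low}).
#' @export
compare_split_responses <- function(aligned, split,
                                    response_window = c(0, 2),
                                    phases = list(initial = c(0, 1),
                                                  late = c(2, 3))) {
  stopifnot(inherits(aligned, "vip_aligned"))
  labels <- if (inherits(split, "vip_split")) split$labels else split
  stopifnot(length(labels) == dim(aligned$data)[3])
  hi <- which(labels == "high"); lo <- which(labels == "low")
  if (!length(hi) || !length(lo)) stop("both split groups must be non-empty")
  group_mean <- function(win, idx) {
    wi <- window_index(aligned$time, win)
    rowMeans(apply(aligned$data[, wi, idx, drop = FALSE], c(1, 3), mean))
  }
  mh <- group_mean(response_window, hi)
  ml <- group_mean(response_window, lo)
  p <- if (length(mh) >= 2 && stats::sd(mh - ml) > 0) {
    stats::t.test(mh, ml, paired = TRUE)$p.value
  } else if (all(mh == ml)) 1 else NA_real_
  phase <- do.call(rbind, lapply(names(phases), function(ph) {
    h <- group_mean(phases[[ph]], hi); l <- group_mean(phases[[ph]], lo)
    data.frame(phase = ph, mean_high = mean(h), mean_low = mean(l),
               diff = mean(h - l),
               p_value = if (stats::sd(h - l) > 0) {
                 stats::t.test(h, l, paired = TRUE)$p.value
               } else if (all(h == l)) 1 else NA_real_)
  }))
  list(mean_high = mean(mh), mean_low = mean(ml),
       sem_high = sem(mh), sem_low = sem(ml), p_value = p, phase = phase,
       per_neuron = cbind(high = mh, low = ml))
}

#' Per-cell correlation with a behavioural trace
#'
#' Pearson correlation of each neuron's whole-session dF/F with a
#' behavioural trace (pupil dP/P or speed) resampled onto the imaging time
#' base; reports the population median and a median split of cells.
#'
#' @param traces dF/F [trace_set()].
#' @param behavior Behaviour vector.
#' @param behavior_time Time axis of `behavior` (s).
#' @return List: `r` (per neuron; `NA` for zero-variance cells), `median_r`,
#'   `cell_group` (`"high"`/`"low"` by median split).
#' @export
percell_behavior_correlation <- function(traces, behavior, behavior_time) {
  stopifnot(inherits(traces, "vip_traces"))
  fs <- traces$sample_rate
  t_img <- (seq_len(ncol(traces$F)) - 1) / fs
  b <- stats::approx(behavior_time, behavior, xout = t_img, rule = 2)$y
  r <- unname(apply(traces$F, 1, function(y) {
    if (stats::sd(y) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(y, b)
  }))
  med <- stats::median(r, na.rm = TRUE)
  list(r = r, median_r = med,
       cell_group = ifelse(is.na(r), NA_character_,
                           ifelse(r > med, "high", "low")))
}

#' Trials without detectable arousal change, and their responses
#'
#' Keeps reinforced trials whose post-reinforcement pupil and speed changes
#' (window 0-1 s after reinforcement vs the pre-tone baseline) do not
#' exceed two SDs of their own baseline fluctuation, then tests whether the
#' population dF/F response on those trials is still above zero
#' (one-sample t-test).
#'
#' @param aligned A [align_trials()] result (reinforced trials).
#' @param trials Trial table rows matching `aligned$trial_index`.
#' @param pupil A [normalize_pupil()] result.
#' @param speed Running-speed trace.
#' @param speed_time Time axis of `speed`.
#' @param window Post-reinforcement window (s), default \[0, 1\].
#' @param baseline_window Pre-tone baseline window (s).
#' @return List: `subset` (aligned-trial indices kept), `n_subset`,
#'   `mean_dff`, `p_value` (one-sided, response > 0; `NA` when the subset
#'   is empty).
#' @export
no_arousal_subset <- function(aligned, trials, pupil, speed, speed_time,
                              window = c(0, 1), baseline_window = c(-2, 0)) {
  stopifnot(inherits(aligned, "vip_aligned"), inherits(pupil, "vip_pupil"))
  fs_b <- pupil$sample_rate
  rows <- trials[aligned$trial_index, ]
  sp <- smooth_gaussian(abs(speed), 0.1, sample_rate = fs_b)
  keep <- logical(nrow(rows))
  for (j in seq_len(nrow(rows))) {
    ev <- rows$reinforcement_onset[j]
    if (is.na(ev)) ev <- rows$tone_onset[j] + aligned$mean_reaction_time
    t0 <- rows$tone_onset[j]
    bsel <- pupil$time >= t0 + baseline_window[1] &
      pupil$time < t0 + baseline_window[2]
    esel <- pupil$time >= ev + window[1] & pupil$time < ev + window[2]
    d_p <- mean(pupil$P[esel]) - mean(pupil$P[bsel])
    s_p <- stats::sd(pupil$P[bsel])
    bs <- speed_time >= t0 + baseline_window[1] &
      speed_time < t0 + baseline_window[2]
    es <- speed_time >= ev + window[1] & speed_time < ev + window[2]
    d_s <- mean(sp[es]) - mean(sp[bs])
    s_s <- stats::sd(sp[bs])
    keep[j] <- d_p <= 2 * s_p & d_s <= 2 * s_s
  }
  subset <- which(keep)
  if (!length(subset)) {
    return(list(subset = integer(0), n_subset = 0L, mean_dff = NA_real_,
                p_value = NA_real_))
  }
  wi <- window_index(aligned$time, window)
  bi <- window_index(aligned$time, baseline_window)
  resp <- vapply(subset, function(j) {
    mean(aligned$data[, wi, j]) - mean(aligned$data[, bi, j])
  }, numeric(1))
  p <- if (length(resp) >= 2 && stats::sd(resp) > 0) {
    stats::t.test(resp, alternative = "greater")$p.value
  } else NA_real_
  list(subset = subset, n_subset = length(subset), mean_dff = mean(resp),
       p_value = p)
}
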