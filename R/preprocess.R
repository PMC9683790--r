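#' Trace container
#'
#' Thin wrapper around a neurons x samples fluorescence matrix with its
#' sample rate and a flag recording whether values are raw fluorescence or
#' dF/F.
#'
#' @param F Numeric matrix, neurons x samples (finite).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param is_dff Logical; `TRUE` when `F` holds dF/F values.
#' @return Object of class `vip_traces`.
#' @export
trace_set <- function(F, sample_rate, is_dff = FALSE) {
  F <- as.matrix(F)
  stopifnot_finite(F, "F")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(F = F, sample_rate = sample_rate, is_dff = is_dff),
            class = "vip_traces")
}

#' Compute dF/F
#'
#' `(F - F0) / F0` with the baseline `F0` estimated either per trial (mean
#' over a window before each tone, the task-data convention) or as a global
#' per-neuron percentile of the whole trace (for continuous recordings).
#' In per-trial mode the baseline applies from that trial's tone (minus the
#' baseline window margin) up to the next trial's; samples before the first
#' trial use the first baseline.
#'
#' @param traces A [trace_set()] (raw fluorescence) or a `vip_session`.
#' @param trials Trial table with `tone_onset`; required for
#'   `method = "per_trial"`.
#' @param method `"per_trial"` or `"percentile"`.
#' @param baseline_window Window (s) relative to tone used as baseline in
#'   per-trial mode; default \[-2, 0\].
#' @param percentile Probability for the percentile baseline.
#' @return A `vip_traces` with `is_dff = TRUE`.
#' @export
compute_dff <- function(traces, trials = NULL,
                        method = c("per_trial", "percentile"),
                        baseline_window = c(-2, 0), percentile = 0.2) {
  if (inherits(traces, "vip_session")) {
    trials <- trials %||% traces$trials
    traces <- trace_set(traces$traces, traces$sample_rate)
  }
  stopifnot(inherits(traces, "vip_traces"))
  method <- match.arg(method)
  F <- traces$F
  fs <- traces$sample_rate
  n <- nrow(F); nsamp <- ncol(F)
  if (method == "percentile") {
    f0 <- apply(F, 1, stats::quantile, probs = percentile, names = FALSE)
    bad <- which(f0 <= 0)
    if (length(bad)) stop("non-positive baseline F0 for neuron(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    dff <- sweep(sweep(F, 1, f0, "-"), 1, f0, "/")
  } else {
    if (is.null(trials) || !nrow(trials)) {
      stop("per-trial baseline requires a trial table")
    }
    tone <- sort(trials$tone_onset)
    seg_start <- c(1L, floor((tone[-1] + baseline_window[1]) * fs) + 1L)
    seg_end <- c(seg_start[-1] - 1L, nsamp)
    dff <- F
    for (k in seq_along(tone)) {
      bidx <- window_index((seq_len(nsamp) - 1) / fs - tone[k],
                           baseline_window)
      f0 <- rowMeans(F[, bidx, drop = FALSE])
      bad <- which(f0 <= 0)
      if (length(bad)) stop("non-positive baseline F0 for neuron(s) ",
                            paste(bad, collapse = ", "), " at trial ", k,
                            call. = FALSE)
      cols <- seg_start[k]:seg_end[k]
      dff[, cols] <- (F[, cols, drop = FALSE] - f0) / f0
    }
  }
  trace_set(dff, fs, is_dff = TRUE)
}

#' Align trials around a behavioural event
#'
#' Cuts a neurons x time x trials tensor from continuous dF/F traces around
#' a per-trial alignment event, interpolating linearly onto a regular
#' relative time grid with t = 0 at the event.  Alignment modes: `"cue"`
#' (tone onset, all trials), `"reinforcement"` (reinforcement onset;
#' Hit/FA only), and `"expected_reinforcement"` (reinforcement onset for
#' Hit/FA; for Miss/CR the expected time
#' `tone + mean reaction time (Hit and FA) + reinforcement delay`).
#' Trials whose window would leave the recording are dropped with a warning.
#'
#' @param traces dF/F [trace_set()] (or a `vip_session`, in which case
#'   per-trial dF/F is computed first).
#' @param trials Trial table.
#' @param mode Alignment mode (see above).
#' @param window `c(t_start, t_end)` in s relative to the event.
#' @param reinforcement_delay Delay used for expected reinforcement (s).
#' @return Object of class `vip_aligned`: `data` (neurons x time x trials),
#'   `time` (relative s, t = 0 on the grid), `trial_types`, `trial_index`,
#'   `window`, `mode`, `sample_rate`.
#' @export
align_trials <- function(traces, trials = NULL,
                         mode = c("expected_reinforcement", "reinforcement",
                                  "cue"),
                         window = c(-2, 4), reinforcement_delay = 0.5) {
  if (inherits(traces, "vip_session")) {
    trials <- trials %||% traces$trials
    reinforcement_delay <- traces$config$reinforcement_delay
    traces <- compute_dff(traces)
  }
  stopifnot(inherits(traces, "vip_traces"), !is.null(trials))
  if (!isTRUE(traces$is_dff)) stop("align_trials expects dF/F traces")
  mode <- match.arg(mode)
  fs <- traces$sample_rate
  reinforced <- trials$type %in% c("Hit", "FA")
  mean_rt <- mean(trials$reaction_time[reinforced])
  event <- switch(mode,
    cue = trials$tone_onset,
    reinforcement = ifelse(reinforced, trials$reinforcement_onset, NA_real_),
    expected_reinforcement = ifelse(
      reinforced, trials$reinforcement_onset,
      trials$tone_onset + mean_rt + reinforcement_delay))
  keep <- which(!is.na(event))
  rel <- (ceiling(window[1] * fs):(ceiling(window[1] * fs) +
            round(diff(window) * fs) - 1L)) / fs
  t_total <- (ncol(traces$F) - 1) / fs
  inside <- event[keep] + rel[1] >= 0 &
    event[keep] + rel[length(rel)] <= t_total
  if (any(!inside)) {
    warning(sum(!inside), " trial(s) dropped: alignment window outside ",
            "the recording", call. = FALSE)
  }
  keep <- keep[inside]
  if (!length(keep)) stop("no alignable trials remain")
  data <- array(NA_real_, c(nrow(traces$F), length(rel), length(keep)))
  for (j in seq_along(keep)) {
    pos <- (event[keep[j]] + rel) * fs + 1
    data[, , j] <- interp_rows(traces$F, pos)
  }
  structure(list(data = data, time = rel,
                 trial_types = trials$type[keep], trial_index = keep,
                 window = window, mode = mode, sample_rate = fs,
                 mean_reaction_time = mean_rt),
            class = "vip_aligned")
}

#' Gaussian smoothing
#'
#' Discrete Gaussian convolution with reflective boundary handling;
#' `sigma = 0` returns the input unchanged.  `NA` values are ignored
#' (renormalised) so blink gaps do not propagate.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation, in seconds when `sample_rate` is
#'   given, otherwise in samples.
#' @param sample_rate Optional sampling rate (Hz).
#' @return Smoothed vector of the same length.
#' @export
smooth_gaussian <- function(x, sigma, sample_rate = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(sample_rate)) sigma <- sigma * sample_rate
  if (sigma == 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(x[pmin(r:1, n)], x, x[pmax(n - (1:r) + 1L, 1L)])
  if (anyNA(xp)) {
    w <- as.numeric(!is.na(xp))
    xp[is.na(xp)] <- 0
    num <- stats::convolve(xp, k, type = "filter")
    den <- stats::convolve(w, k, type = "filter")
    out <- num / den
    out[den == 0] <- NA_real_
    out
  } else {
    stats::convolve(xp, k, type = "filter")
  }
}

#' Response kinetics: peak time and decay constant
#'
#' Locates the post-event peak of an event-aligned mean trace and fits a
#' single exponential `a * exp(-(t - t_peak) / tau)` to the post-peak
#' segment by least squares.  A non-decaying post-peak segment yields
#' `tau_decay = Inf`.
#'
#' @param mean_trace Event-aligned mean dF/F vector.
#' @param sample_rate Sampling rate (Hz).
#' @param time Optional relative time axis; defaults to samples starting at
#'   t = 0.
#' @return Named numeric: `t_peak` (s) and `tau_decay` (s, possibly `Inf`).
#' @export
estimate_kinetics <- function(mean_trace, sample_rate, time = NULL) {
  time <- time %||% ((seq_along(mean_trace) - 1) / sample_rate)
  post <- which(time >= 0)
  y <- mean_trace[post]; tt <- time[post]
  if (max(y) <= 0) stop("trace has no positive post-event maximum")
  ipk <- which.max(y)
  t_peak <- tt[ipk]
  yd <- y[ipk:length(y)]; td <- tt[ipk:length(y)] - t_peak
  if (length(yd) < 3 || yd[length(yd)] >= 0.99 * yd[1]) {
    return(c(t_peak = t_peak, tau_decay = Inf))
  }
  pos <- yd > 0
  fit <- stats::lm(ly ~ tdp, data = data.frame(ly = log(yd[pos]),
                                               tdp = td[pos]))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    return(c(t_peak = t_peak, tau_decay = Inf))
  }
  start <- list(a = yd[1], tau = -1 / slope)
  tau <- tryCatch({
    nl <- minpack.lm::nlsLM(yd ~ a * exp(-td / tau), start = start,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(stats::coef(nl)["tau"])
  }, error = function(e) -1 / slope)
  c(t_peak = unname(t_peak), tau_decay = unname(tau))
}
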