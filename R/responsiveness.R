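#' Classify a neuron's response for one trial type
#'
#' Implements the task-response classifier: per trial, the baseline-window
#' mean is subtracted; the per-trial response-window means are then tested
#' against zero with two one-tailed one-sample t-tests (each at
#' `alpha`), giving `"activated"` when the positive tail is significant,
#' `"suppressed"` when the negative tail is, otherwise `"none"`.  A
#' Lilliefors normality test on the per-trial means is recorded as metadata
#' but does not gate the classification.
#'
#' @param aligned A [align_trials()] result.
#' @param neuron Neuron index.
#' @param trial_type One of `"Hit"`, `"FA"`, `"Miss"`, `"CR"`.
#' @param response_window,baseline_window Windows (s) relative to the
#'   alignment event; defaults 0-2 s and -2-0 s.
#' @param alpha Per-tail significance level.
#' @return List: `direction` (`"activated"`, `"suppressed"`, `"none"` or
#'   `"insufficient"` when fewer than 3 trials are available), `p_value`
#'   (smaller tail p), `p_activated`, `p_suppressed`, `normal_flag` and
#'   `lilliefors_p` (NA when too few trials), `amplitude` (mean
#'   baseline-subtracted response, dF/F), `n_trials`.
#' @export
classify_response <- function(aligned, neuron, trial_type,
                              response_window = c(0, 2),
                              baseline_window = c(-2, 0), alpha = 0.05) {
  stopifnot(inherits(aligned, "vip_aligned"))
  k <- which(aligned$trial_types == trial_type)
  if (length(k) < 3) {
    return(list(direction = "insufficient", p_value = NA_real_,
                p_activated = NA_real_, p_suppressed = NA_real_,
                normal_flag = NA, lilliefors_p = NA_real_,
                amplitude = NA_real_, n_trials = length(k)))
  }
  bi <- window_index(aligned$time, baseline_window)
  ri <- window_index(aligned$time, response_window)
  x <- vapply(k, function(j) {
    tr <- aligned$data[neuron, , j]
    mean(tr[ri]) - mean(tr[bi])
  }, numeric(1))
  lil_p <- if (length(x) >= 4 && stats::sd(x) > 0) {
    tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
  } else NA_real_
  if (stats::sd(x) == 0) {
    # degenerate: no variability; call by sign of the common value
    dir <- if (x[1] > 0) "activated" else if (x[1] < 0) "suppressed" else "none"
    return(list(direction = dir, p_value = if (x[1] == 0) 1 else 0,
                p_activated = NA_real_, p_suppressed = NA_real_,
                normal_flag = NA, lilliefors_p = lil_p,
                amplitude = mean(x), n_trials = length(x)))
  }
  p_act <- stats::t.test(x, alternative = "greater")$p.value
  p_sup <- stats::t.test(x, alternative = "less")$p.value
  direction <- if (p_act < alpha) "activated" else
    if (p_sup < alpha) "suppressed" else "none"
  list(direction = direction, p_value = min(p_act, p_sup),
       p_activated = p_act, p_suppressed = p_sup,
       normal_flag = if (is.na(lil_p)) NA else lil_p >= 0.05,
       lilliefors_p = lil_p, amplitude = mean(x), n_trials = length(x))
}

#' Classify every neuron for every trial type
#'
#' @inheritParams classify_response
#' @param trial_types Types to classify (default the four outcomes present).
#' @return Object of class `vip_responsiveness`: a data frame with one row
#'   per neuron x trial type (`neuron`, `trial_type`, `direction`,
#'   `p_value`, `normal_flag`, `amplitude`, `n_trials`) plus a
#'   `responsive_any` attribute (logical per neuron).
#' @export
classify_all <- function(aligned, trial_types = NULL,
                         response_window = c(0, 2),
                         baseline_window = c(-2, 0), alpha = 0.05) {
  trial_types <- trial_types %||% intersect(c("Hit", "FA", "Miss", "CR"),
                                            unique(aligned$trial_types))
  n <- dim(aligned$data)[1]
  rows <- list()
  for (tt in trial_types) {
    for (i in seq_len(n)) {
      cl <- classify_response(aligned, i, tt, response_window,
                              baseline_window, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = i, trial_type = tt, direction = cl$direction,
        p_value = cl$p_value, normal_flag = cl$normal_flag,
        lilliefors_p = cl$lilliefors_p, amplitude = cl$amplitude,
        n_trials = cl$n_trials, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  resp <- tapply(res$direction != "none" & res$direction != "insufficient",
                 res$neuron, any)
  structure(res, responsive_any = as.logical(resp),
            class = c("vip_responsiveness", "data.frame"))
}

#' Trial-wise activity matrix
#'
#' A neuron counts as active on a trial when the mean dF/F of the 250 ms
#' around the post-event peak exceeds the trial's baseline mean by strictly
#' more than two baseline standard deviations (the SD of that trial's own
#' baseline samples).
#'
#' @inheritParams classify_response
#' @param peak_halfwidth Half-width (s) of the averaging window around the
#'   peak (250 ms total by default), truncated at the response window edges.
#' @param n_sd SD multiple of the activity criterion.
#' @return Binary matrix neurons x trials with trial types as an attribute.
#' @export
trial_activity <- function(aligned, response_window = c(0, 2),
                           baseline_window = c(-2, 0),
                           peak_halfwidth = 0.125, n_sd = 2) {
  stopifnot(inherits(aligned, "vip_aligned"))
  bi <- window_index(aligned$time, baseline_window)
  ri <- window_index(aligned$time, response_window)
  if (!length(bi) || !length(ri)) stop("windows outside the aligned range")
  n <- dim(aligned$data)[1]; K <- dim(aligned$data)[3]
  A <- matrix(0L, n, K)
  for (j in seq_len(K)) {
    for (i in seq_len(n)) {
      tr <- aligned$data[i, , j]
      base <- tr[bi]
      ipk <- ri[which.max(tr[ri])]
      pk <- ri[abs(aligned$time[ri] - aligned$time[ipk]) <= peak_halfwidth +
                 1e-9]
      excess <- mean(tr[pk]) - mean(base)
      A[i, j] <- as.integer(excess > n_sd * stats::sd(base))
    }
  }
  structure(A, trial_types = aligned$trial_types, class = "vip_activity")
}

#' Synchronicity: fraction of neurons active per trial
#'
#' @param activity A [trial_activity()] matrix.
#' @return Numeric vector (length = trials) of active fractions in \[0, 1\],
#'   with a `by_type` attribute giving mean and SEM per trial type.
#' @export
synchronicity <- function(activity) {
  stopifnot(nrow(activity) >= 1)
  s <- colMeans(unclass(activity))
  tt <- attr(activity, "trial_types")
  by_type <- NULL
  if (!is.null(tt)) {
    by_type <- do.call(rbind, lapply(split(s, tt), function(v) {
      data.frame(mean = mean(v), sem = sem(v), n = length(v))
    }))
  }
  structure(s, by_type = by_type)
}

#' Reliability: fraction of active trials per neuron
#'
#' @param activity A [trial_activity()] matrix.
#' @param trial_type Optional trial type to restrict to.
#' @return Numeric vector (length = neurons) of fractions in \[0, 1\].
#' @export
reliability <- function(activity, trial_type = NULL) {
  A <- unclass(activity)
  if (!is.null(trial_type)) {
    k <- which(attr(activity, "trial_types") == trial_type)
    if (!length(k)) stop("no trials of type ", trial_type)
    A <- A[, k, drop = FALSE]
  }
  rowMeans(A)
}

#' Stability of the active fraction across trials
#'
#' Per-trial active fraction in temporal order plus its least-squares trend.
#'
#' @param activity A [trial_activity()] matrix (trials in temporal order).
#' @param ordering Optional explicit trial ordering.
#' @return List: `fraction` (per trial), `slope` (fraction per trial;
#'   `NA` for a single trial), `slope_ci` (95% interval), `p_value`.
#' @export
stability <- function(activity, ordering = NULL) {
  frac <- colMeans(unclass(activity))
  if (!is.null(ordering)) frac <- frac[order(ordering)]
  if (length(frac) < 2) {
    return(list(fraction = frac, slope = NA_real_,
                slope_ci = c(NA_real_, NA_real_), p_value = NA_real_))
  }
  idx <- seq_along(frac)
  fit <- stats::lm(frac ~ idx)
  ci <- tryCatch(stats::confint(fit)[2, ], error = function(e) c(NA, NA))
  list(fraction = frac, slope = unname(stats::coef(fit)[2]),
       slope_ci = unname(ci),
       p_value = summary(fit)$coefficients[2, 4])
}

#' Responder category table
#'
#' Cross-tabulates reward (Hit) and punishment (FA) activation into the
#' mutually exclusive categories `both`, `reward_only`, `punishment_only`
#' and `none`, plus the (non-exclusive) count of neurons activated in all
#' four trial types.
#'
#' @param results A [classify_all()] result containing Hit and FA rows.
#' @return List with `counts`, `fractions` and `n_neurons`.
#' @export
category_table <- function(results) {
  stopifnot(inherits(results, "vip_responsiveness"))
  act <- function(tt) {
    r <- results[results$trial_type == tt, ]
    r$direction[order(r$neuron)] == "activated"
  }
  if (!all(c("Hit", "FA") %in% results$trial_type)) {
    stop("category_table needs Hit and FA classifications")
  }
  rew <- act("Hit"); pun <- act("FA")
  counts <- c(both = sum(rew & pun), reward_only = sum(rew & !pun),
              punishment_only = sum(!rew & pun), none = sum(!rew & !pun))
  all_types <- if (all(c("Miss", "CR") %in% results$trial_type)) {
    sum(rew & pun & act("Miss") & act("CR"))
  } else NA_integer_
  counts <- c(counts, all_types = all_types)
  n <- length(rew)
  list(counts = counts, fractions = counts / n, n_neurons = n)
}

#' Pearson correlation of reward and punishment amplitudes
#'
#' @param hit_amps,fa_amps Paired per-neuron mean response amplitudes.
#' @return Pearson R in \[-1, 1\], or `NA` when either vector has zero
#'   variance.
#' @export
amplitude_correlation <- function(hit_amps, fa_amps) {
  stopifnot(length(hit_amps) == length(fa_amps), length(hit_amps) >= 3,
            all(is.finite(hit_amps)), all(is.finite(fa_amps)))
  if (stats::sd(hit_amps) == 0 || stats::sd(fa_amps) == 0) return(NA_real_)
  stats::cor(hit_amps, fa_amps)
}

#' Partition of amplitude variability: cell-to-cell vs inter-individual
#'
#' For each session the coefficient of variation (`CV = SD/mean`, sample SD)
#' of peak amplitudes over cells is computed and averaged across sessions
#' (cell-to-cell CV); the CV over session-mean amplitudes gives the
#' inter-individual CV.
#'
#' @param amps Numeric vector of peak amplitudes.
#' @param session Session identifier per amplitude.
#' @return List: `cell_to_cell` (mean of per-session CVs), `per_session`
#'   CVs, `inter_individual` CV.  Groups with non-positive means yield `NA`.
#' @export
cv_partition <- function(amps, session) {
  stopifnot(length(amps) == length(session))
  groups <- split(amps, session)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("cv_partition needs >= 2 sessions with >= 2 cells each")
  }
  cv <- function(x) {
    m <- mean(x)
    if (m <= 0) NA_real_ else stats::sd(x) / m
  }
  per_session <- vapply(groups, cv, numeric(1))
  session_means <- vapply(groups, mean, numeric(1))
  list(cell_to_cell = mean(per_session, na.rm = TRUE),
       per_session = per_session,
       inter_individual = cv(session_means))
}
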