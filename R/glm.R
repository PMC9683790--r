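#' Water-delivery regressor from the session lick-rate curve
#'
#' Each water delivery contributes a kernel that rises as a Gaussian from
#' the delivery time, peaks when the average lick rate peaks (before its
#' plateau), then decays linearly to baseline at the time the lick-rate
#' plateau has decayed 5% from its peak.  Kernels from overlapping
#' deliveries sum.  When the session has no licks, a fixed 2-s kernel
#' (peak at 0.5 s) is used instead and a message is emitted.
#'
#' @param delivery_times Water delivery times (s).
#' @param lick_rate List with `time` (s relative to delivery) and `rate`
#'   (licks/s), e.g. from [lick_rate_curve()]; `NULL` triggers the fixed
#'   fallback kernel.
#' @param time Session time axis (s) on which the regressor is sampled.
#' @return Numeric regressor, same length as `time`.
#' @export
water_kernel <- function(delivery_times, lick_rate, time) {
  if (is.null(lick_rate) || !length(lick_rate$rate) ||
      max(lick_rate$rate) <= 0) {
    message("no licks available: falling back to a fixed 2-s water kernel")
    t_peak <- 0.5; t_end <- 2
  } else {
    rate <- lick_rate$rate; lt <- lick_rate$time
    post <- which(lt >= 0)
    ipk <- post[which.max(rate[post])]
    t_peak <- lt[ipk]
    after <- which(lt > lt[ipk])
    drop5 <- after[rate[after] <= 0.95 * rate[ipk]]
    t_end <- if (length(drop5)) lt[drop5[1]] else lt[length(lt)]
    if (t_peak <= 0) t_peak <- lt[min(ipk + 1L, length(lt))]
    if (t_end <= t_peak) t_end <- t_peak + 0.5
  }
  single_event_kernel(delivery_times, time, t_peak, t_end)
}

# Gaussian rise to t_peak then linear decay to zero at t_end, summed over
# events.
single_event_kernel <- function(events, time, t_peak, t_end) {
  out <- numeric(length(time))
  sigma <- t_peak / 3
  for (ev in events) {
    s <- time - ev
    k <- numeric(length(time))
    rise <- s >= 0 & s <= t_peak
    k[rise] <- exp(-(s[rise] - t_peak)^2 / (2 * sigma^2))
    dec <- s > t_peak & s < t_end
    k[dec] <- 1 - (s[dec] - t_peak) / (t_end - t_peak)
    out <- out + k
  }
  out
}

#' Average lick-rate curve aligned to water delivery
#'
#' @param session A `vip_session`.
#' @param window Window (s) relative to delivery.
#' @param bin Bin width (s).
#' @return List with `time` (bin centres, s relative to delivery) and
#'   `rate` (licks/s, lightly smoothed), or `NULL` when the session has no
#'   licks on rewarded trials.
#' @export
lick_rate_curve <- function(session, window = c(-1, 4), bin = 0.1) {
  hits <- which(session$trials$type == "Hit")
  lick_times <- attr(session$trials, "lick_times")
  if (!length(hits) || is.null(lick_times)) return(NULL)
  edges <- seq(window[1], window[2], by = bin)
  counts <- numeric(length(edges) - 1)
  for (j in hits) {
    rel <- lick_times[[j]] - session$trials$reinforcement_onset[j]
    counts <- counts + graphics::hist(rel[rel >= window[1] & rel < window[2]],
                                      breaks = edges, plot = FALSE)$counts
  }
  rate <- counts / (length(hits) * bin)
  if (all(rate == 0)) return(NULL)
  list(time = edges[-1] - bin / 2, rate = smooth_gaussian(rate, 1))
}

#' Air-puff regressor
#'
#' A Gaussian kernel starting at puff onset and peaking 0.2 s later (the
#' valve-closure time); the width is chosen so the kernel is essentially
#' zero (below 1% of peak) at onset.
#'
#' @param puff_times Air-puff onset times (s).
#' @param time Session time axis (s).
#' @param peak_delay Time from onset to kernel peak (s).
#' @param sigma Gaussian SD (s).
#' @return Numeric regressor, same length as `time`.
#' @export
airpuff_kernel <- function(puff_times, time, peak_delay = 0.2,
                           sigma = 0.064) {
  out <- numeric(length(time))
  for (ev in puff_times) {
    s <- time - ev
    k <- exp(-(s - peak_delay)^2 / (2 * sigma^2))
    k[s < 0] <- 0
    k[s > peak_delay + 4 * sigma] <- 0
    out <- out + k
  }
  out
}

#' Build the behavioural design matrix
#'
#' Assembles the standard predictors at the imaging sample rate: a 0.5-s
#' boxcar at each auditory cue, the [water_kernel()] and
#' [airpuff_kernel()] event regressors, the Gauss-filtered pupil trace and
#' the absolute running speed (block-mean downsampled when the behaviour is
#' sampled faster than imaging), plus an optional uniform-random control
#' column.  All retained columns are z-scored; constant columns are
#' excluded with a message.
#'
#' @param session A `vip_session`.
#' @param include_random Add a `random` column of uniform draws in \[0, 1\].
#' @param seed Seed for the random column.
#' @param pupil_sigma Pupil Gaussian filter SD (s).
#' @return Object of class `vip_design`: `X` (samples x predictors,
#'   standardized), `means`, `sds`, `columns`, `time`.
#' @export
build_design <- function(session, include_random = FALSE, seed = 1,
                         pupil_sigma = 0.1) {
  stopifnot(inherits(session, "vip_session"))
  fs <- session$sample_rate
  time <- session$time
  beh <- session$behavior
  trials <- session$trials
  cue <- numeric(length(time))
  for (t0 in trials$tone_onset) cue[time >= t0 & time < t0 + 0.5] <- 1
  water_t <- trials$reinforcement_onset[trials$type == "Hit"]
  puff_t <- trials$reinforcement_onset[trials$type == "FA"]
  water <- water_kernel(water_t, lick_rate_curve(session), time)
  puff <- airpuff_kernel(puff_t, time)
  pup <- normalize_pupil(beh$pupil, beh$time, trials,
                         sigma = pupil_sigma)$P
  pup <- downsample_to(pup, beh$time, time)
  spd <- downsample_to(smooth_gaussian(abs(beh$speed), 0.1,
                                       sample_rate = beh$sample_rate),
                       beh$time, time)
  cols <- list(cue = cue, water = water, airpuff = puff, pupil = pup,
               speed = spd)
  if (include_random) {
    cols$random <- with_seed(seed, stats::runif(length(time)))
  }
  keep <- vapply(cols, function(x) stats::sd(x) > 0, logical(1))
  if (any(!keep)) {
    message("constant column(s) excluded: ",
            paste(names(cols)[!keep], collapse = ", "))
  }
  X <- do.call(cbind, cols[keep])
  mu <- colMeans(X); sds <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = mu, scale = sds)
  structure(list(X = Xs, means = mu, sds = sds,
                 columns = colnames(X), time = time),
            class = "vip_design")
}

# Block-mean downsampling of x (on time base t_from) onto t_to; identity
# when the rates match, interpolation when they are incommensurate.
downsample_to <- function(x, t_from, t_to) {
  r <- stats::median(diff(t_to)) / stats::median(diff(t_from))
  if (abs(r - 1) < 1e-9) {
    return(stats::approx(t_from, x, xout = t_to, rule = 2)$y)
  }
  if (abs(r - round(r)) < 1e-6 && r > 1) {
    r <- as.integer(round(r))
    nb <- floor(length(x) / r)
    xb <- colMeans(matrix(x[seq_len(nb * r)], r, nb))
    tb <- colMeans(matrix(t_from[seq_len(nb * r)], r, nb))
    return(stats::approx(tb, xb, xout = t_to, rule = 2)$y)
  }
  stats::approx(t_from, x, xout = t_to, rule = 2)$y
}

#' Cross-validated lasso fit of the population calcium signal
#'
#' Lasso regression of `y` on a standardized design matrix, with the
#' penalty chosen on a log-spaced grid (`1e-4` to `1e1` times the largest
#' penalty that zeroes all weights) by 5-fold cross-validation over
#' contiguous time blocks (respecting temporal autocorrelation).  Variance
#' explained is the mean held-out R-squared at the selected penalty.
#'
#' @param design A [build_design()] result (or plain standardized matrix).
#' @param y Response (population mean dF/F), finite.
#' @param folds Number of contiguous CV folds.
#' @param seed Stored with the fit (fold construction is deterministic).
#' @param nlambda Grid size.
#' @return Object of class `vip_glmfit`: `weights` (named, per predictor),
#'   `intercept`, `lambda`, `variance_explained` (mean held-out R-squared),
#'   `fold_r2`, `lambda_grid`, `seed`.
#' @export
fit_lasso <- function(design, y, folds = 5, seed = 1, nlambda = 50) {
  X <- if (inherits(design, "vip_design")) design$X else as.matrix(design)
  if (!all(is.finite(y))) stop("non-finite values in y")
  n <- nrow(X); p <- ncol(X)
  if (n < 10 * p) stop("need at least 10 rows per column")
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  grid <- exp(seq(log(lam_max * 10), log(lam_max * 1e-4),
                  length.out = nlambda))
  fold_id <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
  fold_mse <- matrix(NA_real_, folds, nlambda)
  fold_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], lambda = grid,
                          standardize = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    err <- sweep(pred, 1, y[!tr], "-")
    fold_mse[f, seq_len(ncol(pred))] <- colMeans(err^2)
  }
  mse <- colMeans(fold_mse)
  best <- which.min(mse)
  lambda <- grid[best]
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], lambda = grid,
                          standardize = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lambda)
    sst <- sum((y[!tr] - mean(y[!tr]))^2)
    fold_r2[f] <- 1 - sum((y[!tr] - pred)^2) / sst
  }
  full <- glmnet::glmnet(X, y, lambda = grid, standardize = FALSE)
  w <- as.numeric(stats::coef(full, s = lambda))[-1]
  names(w) <- colnames(X)
  structure(list(weights = w,
                 intercept = as.numeric(stats::coef(full, s = lambda))[1],
                 lambda = lambda, variance_explained = mean(fold_r2),
                 fold_r2 = fold_r2, lambda_grid = grid, seed = seed),
            class = "vip_glmfit")
}

#' Simulate a population calcium signal with planted predictor weights
#'
#' Builds the behavioural design matrix of a session and generates
#' `y = X w + noise` on the standardized predictors, recording the planted
#' weights; used for encoding-model recovery experiments.  The default
#' weights order the predictors as arousal (pupil) > reward (water) >
#' punishment (air puff) > locomotion speed > auditory cue.
#'
#' @param session A `vip_session`.
#' @param weights Named weights over design columns.
#' @param noise_sd Gaussian noise SD added to `y`.
#' @param seed Seed for the noise.
#' @return List: `y`, `design`, `weights` (as planted, in design-column
#'   order).
#' @export
simulate_population_signal <- function(session,
                                       weights = c(pupil = 0.055,
                                                   water = 0.031,
                                                   airpuff = 0.028,
                                                   speed = 0.020,
                                                   cue = 0.018),
                                       noise_sd = 0.05, seed = 1) {
  design <- build_design(session)
  w <- weights[design$columns]
  if (anyNA(w)) stop("weights must name every design column")
  y <- as.numeric(design$X %*% w) +
    with_seed(seed, stats::rnorm(nrow(design$X), 0, noise_sd))
  list(y = y, design = design, weights = w)
}
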