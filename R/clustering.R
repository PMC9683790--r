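#' Normalise reward-response profiles for clustering
#'
#' Per neuron the trial-averaged Hit (reward) response is z-scored using the
#' mean and SD of the first second of the aligned window, then divided by
#' its maximal amplitude over 0-4 s after reward delivery.  Neurons with
#' zero first-second SD are excluded, as are outliers whose profile norm
#' exceeds `outlier_factor` times the median norm (cells that would
#' disproportionately inflate the reconstruction error).
#'
#' @param aligned A [align_trials()] result (reward-aligned).
#' @param trial_type Trials averaged per neuron (default `"Hit"`).
#' @param norm_window Window (s) whose maximum normalises each profile.
#' @param outlier_factor Profile-norm exclusion multiple (`Inf` disables).
#' @return Object of class `vip_profiles`: matrix kept-neurons x time with
#'   attributes `time`, `kept` (original indices), `excluded` (list by
#'   reason).
#' @export
preprocess_profiles <- function(aligned, trial_type = "Hit",
                                norm_window = c(0, 4), outlier_factor = 5) {
  stopifnot(inherits(aligned, "vip_aligned"))
  k <- which(aligned$trial_types == trial_type)
  if (!length(k)) stop("no trials of type ", trial_type)
  prof <- apply(aligned$data[, , k, drop = FALSE], c(1, 2), mean)
  tfirst <- window_index(aligned$time, c(aligned$window[1],
                                         aligned$window[1] + 1))
  mu <- rowMeans(prof[, tfirst, drop = FALSE])
  sd1 <- apply(prof[, tfirst, drop = FALSE], 1, stats::sd)
  zero_sd <- which(sd1 == 0)
  if (length(zero_sd)) {
    message(length(zero_sd), " profile(s) excluded: zero first-second SD")
  }
  keep <- setdiff(seq_len(nrow(prof)), zero_sd)
  z <- (prof[keep, , drop = FALSE] - mu[keep]) / sd1[keep]
  wi <- window_index(aligned$time, norm_window)
  mx <- apply(abs(z[, wi, drop = FALSE]), 1, max)
  z <- z / mx
  outl <- integer(0)
  if (is.finite(outlier_factor) && nrow(z) >= 3) {
    nrm <- sqrt(rowSums(z^2))
    outl <- which(nrm > outlier_factor * stats::median(nrm))
    if (length(outl)) {
      message(length(outl), " profile(s) excluded as norm outliers")
      keep <- keep[-outl]
      z <- z[-outl, , drop = FALSE]
    }
  }
  structure(z, time = aligned$time, kept = keep,
            excluded = list(zero_sd = zero_sd, outlier = outl),
            norm_window = norm_window, class = "vip_profiles")
}

#' PCA reduction of response profiles
#'
#' Principal components are computed on the post-reward segment of the
#' normalised profiles; the smallest number of components whose cumulative
#' explained variance reaches `var_threshold` is retained.
#'
#' @param profiles A [preprocess_profiles()] matrix (or plain matrix with a
#'   `time` attribute).
#' @param var_threshold Cumulative variance threshold (default 0.90).
#' @param segment Window (s) analysed (default 0-4 s post reward).
#' @return List: `scores` (neurons x retained), `loadings`, `n_retained`,
#'   `var_explained` (per component), `segment`.
#' @export
pca_reduce <- function(profiles, var_threshold = 0.90, segment = c(0, 4)) {
  time <- attr(profiles, "time")
  X <- unclass(profiles)
  if (!is.null(time)) X <- X[, window_index(time, segment), drop = FALSE]
  if (nrow(X) < 2) stop("pca_reduce needs at least 2 profiles")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  r <- which(cumsum(ve) >= var_threshold - 1e-12)[1]
  list(scores = pc$x[, seq_len(r), drop = FALSE],
       loadings = pc$rotation[, seq_len(r), drop = FALSE],
       n_retained = r, var_explained = ve, segment = segment)
}

#' K-means clustering with k-means++ replicates
#'
#' Runs `replicates` k-means fits, each seeded with a k-means++
#' initialisation, and keeps the solution with the lowest total
#' within-cluster sum of squares.  Deterministic given `seed`.
#'
#' @param scores Numeric matrix (points x features), e.g. PC scores.
#' @param k Number of clusters (default 5).
#' @param replicates Number of replicate initialisations (default 5).
#' @param seed Integer seed.
#' @return List of class `vip_clusters`: `labels`, `centers`,
#'   `tot_withinss`, `k`.
#' @export
kmeans_cluster <- function(scores, k = 5, replicates = 5, seed = 1) {
  scores <- as.matrix(scores)
  if (nrow(unique(scores)) < k) {
    stop("fewer than k distinct points; cannot form ", k, " clusters")
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(replicates)) {
      init <- kmeanspp_init(scores, k)
      fit <- suppressWarnings(
        stats::kmeans(scores, centers = init, iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(labels = best$cluster, centers = best$centers,
                   tot_withinss = best$tot.withinss, k = k),
              class = "vip_clusters")
  })
}

# k-means++ seeding: iteratively sample centres proportional to squared
# distance from the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  # nudge duplicated centres to keep stats::kmeans happy
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] +
    stats::rnorm(sum(dup) * ncol(X), 0, 1e-8)
  centers
}

#' Cluster mean profiles (feature vectors)
#'
#' @param profiles A [preprocess_profiles()] matrix.
#' @param labels Cluster labels per profile.
#' @return Matrix k x time of cluster mean profiles.
#' @export
cluster_features <- function(profiles, labels) {
  X <- unclass(profiles)
  feats <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(X[labels == l, , drop = FALSE])
  }))
  structure(feats, time = attr(profiles, "time"))
}

#' Project profiles onto cluster features
#'
#' Inner product of each normalised profile with each unit-normalised
#' cluster mean profile.
#'
#' @param profiles Profiles matrix (neurons x time).
#' @param features Cluster mean profiles (k x time).
#' @return Score matrix neurons x k.
#' @export
feature_projection <- function(profiles, features) {
  X <- unclass(profiles); Fm <- unclass(features)
  stopifnot(ncol(X) == ncol(Fm))
  nrm <- sqrt(rowSums(Fm^2))
  nrm[nrm == 0] <- 1
  X %*% t(Fm / nrm)
}

#' Compare feature projections between two cortical areas
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature with the
#' mean difference `area_a - area_b`.
#'
#' @param scores Projection scores (neurons x features).
#' @param areas Area label per neuron.
#' @param area_a,area_b The two areas compared (defaults: first two labels).
#' @return Data frame: `feature`, `mean_diff`, `statistic`, `p_value`.
#' @export
compare_by_area <- function(scores, areas, area_a = NULL, area_b = NULL) {
  lv <- unique(areas)
  if (length(lv) < 2) stop("compare_by_area needs at least two areas")
  area_a <- area_a %||% lv[1]; area_b <- area_b %||% lv[2]
  a <- scores[areas == area_a, , drop = FALSE]
  b <- scores[areas == area_b, , drop = FALSE]
  if (nrow(a) < 3 || nrow(b) < 3) stop("need >= 3 cells per area")
  do.call(rbind, lapply(seq_len(ncol(scores)), function(j) {
    w <- stats::wilcox.test(a[, j], b[, j], exact = FALSE)
    data.frame(feature = j, mean_diff = mean(a[, j]) - mean(b[, j]),
               statistic = unname(w$statistic), p_value = w$p.value)
  }))
}

#' Depth distribution per cluster and homogeneity test
#'
#' Empirical CDFs of cortical depth per cluster, with a one-way ANOVA
#' (depth ~ cluster) testing homogeneity.
#'
#' @param labels Cluster labels.
#' @param depths Cortical depths (um), finite.
#' @return List: `ecdf` (named list of functions), `F`, `p_value`
#'   (`NA` for a single cluster).
#' @export
depth_distribution <- function(labels, depths) {
  stopifnot_finite(depths, "depths")
  cdfs <- lapply(split(depths, labels), stats::ecdf)
  if (length(unique(labels)) < 2) {
    return(list(ecdf = cdfs, F = NA_real_, p_value = NA_real_))
  }
  fit <- stats::aov(depths ~ factor(labels))
  s <- summary(fit)[[1]]
  list(ecdf = cdfs, F = s[["F value"]][1], p_value = s[["Pr(>F)"]][1])
}

#' Linear models for cue-response heterogeneity
#'
#' Ordinary least squares of the relative cue response on either the
#' session hit rate or a 4-level region factor (dummy coded), reporting the
#' coefficient of determination and the overall F-test p-value.
#'
#' @param x Predictor: numeric hit rate, or region labels (coerced to a
#'   factor) for the region model.
#' @param y Relative cue response per session.
#' @return List: `r_squared`, `p_value`, `fit` (the `lm` object).
#' @export
regress_cue_response <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 3)
  df <- data.frame(y = y, x = if (is.numeric(x)) x else factor(x))
  if (stats::var(y) == 0) {
    return(list(r_squared = 0, p_value = NA_real_,
                fit = stats::lm(y ~ x, data = df)))
  }
  fit <- stats::lm(y ~ x, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design matrix")
  s <- summary(fit)
  p <- if (s$sigma == 0 || is.null(s$fstatistic)) {
    if (s$r.squared >= 1 - 1e-12) 0 else NA_real_
  } else {
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  }
  list(r_squared = s$r.squared, p_value = p, fit = fit)
}

#' Relative cue response of a session
#'
#' On the session-average Hit trace aligned to the cue, the cue response
#' (peak dF/F between cue onset and the mean reinforcement time) is divided
#' by the reinforcement response (peak after the mean reinforcement time).
#'
#' @param session A `vip_session`.
#' @param window Alignment window (s) around the cue.
#' @return Scalar ratio (cue / reinforcement amplitude).
#' @export
relative_cue_response <- function(session, window = c(-2, 6)) {
  al <- align_trials(session, mode = "cue", window = window)
  k <- which(al$trial_types == "Hit")
  if (!length(k)) stop("session has no Hit trials")
  avg <- colMeans(apply(al$data[, , k, drop = FALSE], c(1, 2), mean))
  t_reinf <- al$mean_reaction_time + session$config$reinforcement_delay
  cue_amp <- max(avg[al$time >= 0 & al$time < t_reinf])
  reinf_amp <- max(avg[al$time >= t_reinf])
  cue_amp / reinf_amp
}
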