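#' Full width at half maximum of an intensity line profile
#'
#' The fluorescence baseline is the mean of the outer 10% of samples (5%
#' at each end); the width is measured at half of the baseline-subtracted
#' peak, with both half-crossings located by linear interpolation between
#' the bracketing samples.  Invariant to adding a constant and to positive
#' rescaling of the intensity.
#'
#' @param profile Intensity vector along the measurement line.
#' @param pixel_size Sample spacing (um/pixel).
#' @return FWHM in um.
#' @export
fwhm <- function(profile, pixel_size = 1) {
  n <- length(profile)
  stopifnot(n >= 5)
  k <- max(1L, floor(0.05 * n))
  base <- mean(profile[c(seq_len(k), (n - k + 1L):n)])
  ipk <- which.max(profile)
  peak <- profile[ipk]
  if (peak <= base) stop("profile peak does not exceed the baseline")
  half <- base + (peak - base) / 2
  cross <- function(i) {
    # half-crossing between samples i and i + 1, by linear interpolation
    i + (half - profile[i]) / (profile[i + 1L] - profile[i])
  }
  left <- which(profile[seq_len(ipk)] < half)
  right <- which(profile[ipk:n] < half) + ipk - 1L
  if (!length(left) || !length(right)) {
    stop("half level is not crossed on both sides of the peak")
  }
  xl <- cross(max(left))
  xr <- cross(min(right) - 1L)
  (xr - xl) * pixel_size
}

#' Simulate a soma intensity line profile
#'
#' Gaussian intensity bump whose FWHM equals the requested diameter, on a
#' constant background with optional noise; used to exercise [fwhm()]
#' against known ground truth.
#'
#' @param diameter Soma diameter (um).
#' @param pixel_size Sampling (um/pixel).
#' @param extent Profile half-length (um).
#' @param baseline Background intensity.
#' @param amplitude Peak intensity above background.
#' @param noise_sd Intensity noise SD.
#' @param seed Integer seed.
#' @return List: `profile`, `pixel_size`.
#' @export
simulate_soma_profile <- function(diameter, pixel_size = 0.2, extent = 12,
                                  baseline = 10, amplitude = 100,
                                  noise_sd = 0, seed = 1) {
  x <- seq(-extent, extent, by = pixel_size)
  sigma <- diameter / (2 * sqrt(2 * log(2)))
  y <- baseline + amplitude * exp(-x^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- y + with_seed(seed, stats::rnorm(length(x), 0,
                                                          noise_sd))
  list(profile = y, pixel_size = pixel_size)
}

#' Bimodality of the soma-diameter distribution
#'
#' Fits one- and two-component Gaussian mixtures to the binned diameter
#' histogram by least squares and compares them with an
#' extra-sum-of-squares F-test; reports the two-component fit's R-squared.
#' A two-component fit whose minor component carries under 1% of the
#' fitted mass is reported as unimodal.
#'
#' @param diameters Soma diameters (um), n >= 30.
#' @param bin_width Histogram bin width (um, default 0.5).
#' @return List: `means`, `sds`, `amplitudes` (two-component fit, sorted by
#'   mean), `r_squared`, `F`, `p_value`, `bimodal` (logical),
#'   `single_fit` (one-component parameters).
#' @export
diameter_bimodality <- function(diameters, bin_width = 0.5) {
  diameters <- diameters[is.finite(diameters)]
  if (length(diameters) < 30) stop("need at least 30 diameters")
  edges <- seq(floor(min(diameters) / bin_width) * bin_width,
               ceiling(max(diameters) / bin_width) * bin_width,
               by = bin_width)
  h <- graphics::hist(diameters, breaks = edges, plot = FALSE)
  x <- h$mids; y <- h$counts
  g <- function(x, a, mu, s) a * exp(-(x - mu)^2 / (2 * s^2))
  # both models are fitted on Anscombe-transformed counts, sqrt(y + 3/8),
  # whose variance is approximately constant under Poisson bin counts, so
  # the extra-sum-of-squares F-test holds close to its nominal level
  ys <- sqrt(y + 0.375)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300)
  # one component
  st1 <- list(a = max(y), mu = mean(diameters), s = stats::sd(diameters))
  f1 <- minpack.lm::nlsLM(ys ~ sqrt(g(x, a, mu, s) + 0.375), start = st1,
                          lower = c(0, min(x), bin_width / 4),
                          control = ctrl)
  ss1 <- sum((ys - stats::predict(f1))^2)
  # two components, initialised from a 2-means split of the sample with a
  # quantile-based fallback start
  km <- stats::kmeans(matrix(diameters), centers = matrix(range(diameters)))
  mus <- sort(km$centers)
  starts <- list(
    list(a1 = max(y), mu1 = mus[1], s1 = max(stats::sd(
           diameters[km$cluster == which.min(km$centers)]), bin_width),
         a2 = max(y), mu2 = mus[2], s2 = max(stats::sd(
           diameters[km$cluster == which.max(km$centers)]), bin_width)),
    list(a1 = max(y), mu1 = unname(stats::quantile(diameters, 0.25)),
         s1 = stats::sd(diameters) / 2,
         a2 = max(y), mu2 = unname(stats::quantile(diameters, 0.75)),
         s2 = stats::sd(diameters) / 2))
  f2 <- NULL
  for (st2 in starts) {
    f2 <- tryCatch(
      minpack.lm::nlsLM(ys ~ sqrt(g(x, a1, mu1, s1) + g(x, a2, mu2, s2) +
                                    0.375),
                        start = st2,
                        lower = c(0, min(x), bin_width / 4, 0, min(x),
                                  bin_width / 4),
                        control = ctrl),
      error = function(e) NULL)
    if (!is.null(f2)) break
  }
  if (is.null(f2)) {
    # the two-component model cannot be fitted: report the unimodal fit
    cf1 <- stats::coef(f1)
    return(list(means = rep(unname(cf1["mu"]), 2),
                sds = rep(unname(cf1["s"]), 2),
                amplitudes = c(unname(cf1["a"]), 0),
                r_squared = NA_real_, F = NA_real_, p_value = 1,
                bimodal = FALSE, single_fit = cf1))
  }
  ss2 <- sum((ys - stats::predict(f2))^2)
  cf <- stats::coef(f2)
  ord <- order(c(cf["mu1"], cf["mu2"]))
  means <- c(cf["mu1"], cf["mu2"])[ord]
  sds <- c(cf["s1"], cf["s2"])[ord]
  amps <- c(cf["a1"], cf["a2"])[ord]
  mass <- amps * sds
  degenerate <- min(mass) / sum(mass) < 0.01
  df2 <- length(y) - 6
  Fst <- if (df2 > 0 && ss2 > 0) ((ss1 - ss2) / 3) / (ss2 / df2) else Inf
  p <- if (is.finite(Fst)) stats::pf(Fst, 3, df2, lower.tail = FALSE) else 0
  ss2_raw <- sum((y - (stats::predict(f2)^2 - 0.375))^2)
  sst <- sum((y - mean(y))^2)
  list(means = unname(means), sds = unname(sds), amplitudes = unname(amps),
       r_squared = 1 - ss2_raw / sst, F = Fst, p_value = p,
       bimodal = !degenerate && p < 0.05,
       single_fit = stats::coef(f1))
}

#' Compare soma diameters between groups
#'
#' Two groups are compared with a two-sided Mann-Whitney test; three or
#' more with a Kruskal-Wallis test.
#'
#' @param ... Numeric vectors of diameters (um), or a single named list.
#' @return List: `test`, `statistic`, `p_value`, `group_means`.
#' @export
compare_diameters <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 3)) stop("each group needs n >= 3")
  if (length(groups) == 2) {
    w <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
    list(test = "mann_whitney", statistic = unname(w$statistic),
         p_value = w$p.value,
         group_means = vapply(groups, mean, numeric(1)))
  } else {
    x <- unlist(groups)
    gl <- factor(rep(seq_along(groups), lengths(groups)))
    kw <- stats::kruskal.test(x, gl)
    list(test = "kruskal_wallis", statistic = unname(kw$statistic),
         p_value = kw$p.value,
         group_means = vapply(groups, mean, numeric(1)))
  }
}
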