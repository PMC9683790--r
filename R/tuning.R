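#' Mean response amplitude per grating direction
#'
#' Averages baseline-subtracted per-trial response amplitudes over repeats
#' for each of the eight grating directions (45 degree spacing).  Negative
#' means are clipped to zero so the selectivity indices stay in \[0, 1\].
#'
#' @param trial_amps Array cells x 8 directions x repeats of per-trial
#'   response amplitudes (dF/F, baseline already subtracted), or a matrix
#'   8 x repeats for one cell.  `NA` marks missing repeats.
#' @param directions Direction labels (degrees).
#' @return Matrix cells x 8 of mean amplitudes (clipped at 0), directions
#'   as column names.
#' @export
direction_responses <- function(trial_amps,
                                directions = seq(0, 315, by = 45)) {
  if (length(dim(trial_amps)) == 2) {
    trial_amps <- array(trial_amps, c(1, dim(trial_amps)))
  }
  stopifnot(length(dim(trial_amps)) == 3)
  if (dim(trial_amps)[2] != length(directions)) {
    stop("expected ", length(directions), " directions")
  }
  reps <- apply(!is.na(trial_amps), c(1, 2), sum)
  if (any(reps < 3)) stop("need >= 3 repeats per direction")
  resp <- apply(trial_amps, c(1, 2), mean, na.rm = TRUE)
  resp <- pmax(resp, 0)
  colnames(resp) <- directions
  resp
}

#' Orientation and direction selectivity indices
#'
#' `OSI = (R_pref - R_ortho) / (R_pref + R_ortho)` and
#' `DSI = (R_pref - R_opp) / (R_pref + R_opp)`, where `R_pref` is the
#' largest direction response, `R_ortho` the mean of the two directions
#' orthogonal to the preferred one, and `R_opp` the response opposite
#' (180 degrees from) the preferred direction.
#'
#' @param resp Numeric vector of 8 mean direction responses (>= 0), in
#'   45-degree steps.
#' @return For `osi()`/`dsi()`, the index (NA when the denominator is 0);
#'   [tuning_summary()] returns the full per-cell table.
#' @export
osi <- function(resp) {
  st <- tuning_stats(resp)
  if (st$r_pref + st$r_ortho == 0) return(NA_real_)
  (st$r_pref - st$r_ortho) / (st$r_pref + st$r_ortho)
}

#' @rdname osi
#' @export
dsi <- function(resp) {
  st <- tuning_stats(resp)
  if (st$r_pref + st$r_opp == 0) return(NA_real_)
  (st$r_pref - st$r_opp) / (st$r_pref + st$r_opp)
}

tuning_stats <- function(resp) {
  stopifnot(length(resp) == 8)
  if (min(resp) < 0) stop("direction responses must be non-negative")
  ip <- which.max(resp)
  wrap <- function(i) ((i - 1) %% 8) + 1
  list(r_pref = resp[ip],
       r_ortho = mean(resp[c(wrap(ip + 2), wrap(ip - 2))]),
       r_opp = resp[wrap(ip + 4)],
       pref_direction = (ip - 1) * 45)
}

#' @rdname osi
#' @param resp_matrix Matrix cells x 8 from [direction_responses()].
#' @export
tuning_summary <- function(resp_matrix) {
  do.call(rbind, lapply(seq_len(nrow(resp_matrix)), function(i) {
    r <- resp_matrix[i, ]
    st <- tuning_stats(r)
    data.frame(cell = i, r_pref = st$r_pref, r_ortho = st$r_ortho,
               r_opp = st$r_opp, pref_direction = st$pref_direction,
               osi = osi(r), dsi = dsi(r), max_amplitude = max(r))
  }))
}

#' Correlate visual tuning with reinforcement responses
#'
#' Pearson correlations (with p-values) of the visual response maximum,
#' OSI and DSI against per-cell reinforcement response amplitudes.
#'
#' @param tuning A [tuning_summary()] data frame.
#' @param reinforcement_amps Per-cell reinforcement amplitudes (same cells).
#' @return Data frame: `measure`, `r`, `p_value`, `n`.
#' @export
tuning_vs_reinforcement <- function(tuning, reinforcement_amps) {
  stopifnot(nrow(tuning) == length(reinforcement_amps))
  if (nrow(tuning) < 3) stop("need at least 3 cells")
  do.call(rbind, lapply(c("max_amplitude", "osi", "dsi"), function(m) {
    x <- tuning[[m]]
    ok <- is.finite(x) & is.finite(reinforcement_amps)
    ct <- stats::cor.test(x[ok], reinforcement_amps[ok])
    data.frame(measure = m, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok))
  }))
}

#' Simulate cosine-tuned visual responses
#'
#' Per cell the mean response to direction `theta` is
#' `peak * (1 - m * (1 - cos(theta - theta_pref)) / 2)`, i.e. the response
#' opposite the preferred direction is `(1 - m)` times the peak; the
#' analytic direction selectivity is then `DSI = m / (2 - m)`.  Gaussian
#' trial noise is added.  `sharp = TRUE` draws pyramidal-like modulation
#' depths near 1 for contrast experiments.
#'
#' @param n_cells Number of cells.
#' @param repeats Trials per direction.
#' @param peak Mean peak amplitude (dF/F).
#' @param modulation Modulation depth m in \[0, 1\] (scalar or per cell);
#'   ignored when `sharp = TRUE`.
#' @param noise_sd Per-trial amplitude noise.
#' @param sharp Draw sharply tuned cells.
#' @param seed Integer seed.
#' @return List: `trial_amps` (cells x 8 x repeats), `truth` (data frame
#'   with `pref_direction`, `modulation`, `peak`).
#' @export
simulate_tuning <- function(n_cells = 50, repeats = 10, peak = 0.3,
                            modulation = 0.3, noise_sd = 0.05,
                            sharp = FALSE, seed = 1) {
  with_seed(seed, {
    dirs <- seq(0, 315, by = 45)
    pref <- sample(dirs, n_cells, replace = TRUE)
    m <- if (sharp) stats::runif(n_cells, 0.8, 1) else
      rep_len(modulation, n_cells)
    pk <- peak * stats::rlnorm(n_cells, 0, 0.3)
    amps <- array(NA_real_, c(n_cells, 8, repeats))
    for (i in seq_len(n_cells)) {
      mu <- pk[i] * (1 - m[i] * (1 - cos((dirs - pref[i]) * pi / 180)) / 2)
      amps[i, , ] <- mu + stats::rnorm(8 * repeats, 0, noise_sd)
    }
    list(trial_amps = amps,
         truth = data.frame(pref_direction = pref, modulation = m,
                            peak = pk))
  })
}
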