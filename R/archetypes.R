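#' Temporal response archetypes
#'
#' Five canonical temporal profiles of reward-evoked VIP interneuron calcium
#' responses: `"fast"`, `"delayed"`, `"sustained"`, `"biphasic"` and
#' `"slow"`.  Each is a causal, non-negative waveform built from a
#' double-exponential (difference of exponentials) family with GCaMP6f-like
#' rise/decay kinetics, peak-normalised to 1.
#'
#' Time constants (rise / decay, seconds): fast 0.1 / 0.5; delayed as fast
#' with a 0.5 s onset latency; sustained 0.1 / 3; slow 1 / 5.  The biphasic
#' profile adds to the fast lobe a second, broader lobe peaking near 2 s.
#'
#' @param name One of `"fast"`, `"delayed"`, `"sustained"`, `"biphasic"`,
#'   `"slow"`.
#' @param t Numeric vector of non-negative, uniformly sampled times (s).
#' @return Numeric vector of the same length as `t`: the archetype waveform
#'   in dF/F units, non-negative, with maximum 1 (when the support of the
#'   kernel intersects `t`).
#' @examples
#' t <- seq(0, 8, by = 0.05)
#' k <- archetype_kernel("fast", t)
#' stopifnot(k[1] == 0, max(k) == 1)
#' @export
archetype_kernel <- function(name, t) {
  if (length(name) != 1L || !name %in% vip_archetypes()) {
    stop("unknown archetype '", paste(name, collapse = ","),
         "'; valid labels: ", paste(vip_archetypes(), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.numeric(t), all(t >= -1e-12))
  k <- archetype_raw(name, t)
  m <- max(k)
  if (m > 0) k / m else k
}

#' @rdname archetype_kernel
#' @export
vip_archetypes <- function() c("fast", "delayed", "sustained", "biphasic", "slow")

# Unnormalised archetype waveform (shared by archetype_kernel and the
# session generator, which rescales by the continuous-time peak so that
# events can be planted at fractional-sample times).
archetype_raw <- function(name, t) {
  switch(name,
    fast      = dexp_kernel(t, 0.1, 0.5),
    delayed   = dexp_kernel(t, 0.1, 0.5, onset = 0.5),
    sustained = dexp_kernel(t, 0.1, 3),
    biphasic  = dexp_kernel(t, 0.1, 0.5) +
                0.6 * dexp_kernel(t, 0.3, 1, onset = 1.48),
    slow      = dexp_kernel(t, 1, 5)
  )
}

# Continuous-time peak values, memoised at load time on a 1 ms grid.
archetype_peak <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tg <- seq(0, 12, by = 1e-3)
      cache <<- vapply(vip_archetypes(), function(nm) max(archetype_raw(nm, tg)),
                       numeric(1))
    }
    cache
  }
})

# Difference-of-exponentials kernel, zero before `onset`.
dexp_kernel <- function(t, tau_rise, tau_decay, onset = 0) {
  s <- t - onset
  k <- exp(-s / tau_decay) - exp(-s / tau_rise)
  k[s <= 0] <- 0
  pmax(k, 0)
}
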