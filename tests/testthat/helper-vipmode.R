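# Shared fixtures and small independent oracles.

# Adjusted Rand index (independent of the clustering implementation).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  e <- si * sj / n2
  (sij - e) / ((si + sj) / 2 - e)
}

# Hand-built aligned object (neurons x time x trials) for toy cases.
toy_aligned <- function(data, time, trial_types, sample_rate = 20) {
  structure(list(data = data, time = time, trial_types = trial_types,
                 trial_index = seq_along(trial_types),
                 window = range(time) + c(0, diff(time[1:2])),
                 mode = "reinforcement", sample_rate = sample_rate,
                 mean_reaction_time = 0.5),
            class = "vip_aligned")
}

# Null aligned data: pure noise, no planted response.
null_aligned <- function(n_neurons, n_trials = 20, fs = 20, noise = 0.1) {
  ntime <- 4 * fs
  data <- array(stats::rnorm(n_neurons * ntime * n_trials, 0, noise),
                c(n_neurons, ntime, n_trials))
  toy_aligned(data, seq(-2, 2 - 1 / fs, by = 1 / fs),
              rep("Hit", n_trials), fs)
}

# Session cache: default-condition sessions are reused across test files.
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(key, ...) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- generate_session(session_config(...))
  }
  .session_cache[[key]]
}
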