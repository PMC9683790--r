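#' Linear time warp to a fixed length
#'
#' Linearly interpolates a segment (e.g. the reaction-time period of one
#' trial) onto `target_len` uniformly spaced points spanning the segment.
#' Endpoints are preserved exactly.
#'
#' @param segment Numeric vector, length >= 2.
#' @param target_len Output length (default 30 points spanning 1.5 s).
#' @return Numeric vector of length `target_len`.
#' @export
time_warp <- function(segment, target_len = 30) {
  n <- length(segment)
  if (n < 2) stop("time_warp needs a segment of length >= 2")
  if (n == target_len) return(segment)
  stats::approx(seq(0, 1, length.out = n), segment,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Build the trial tensor for component analysis
#'
#' For each session with at least `trials_per_type` trials of every outcome,
#' the dF/F segment of each of the first `trials_per_type` trials per type
#' is extracted over the reaction-time period (tone to reinforcement onset
#' for Hit/FA; tone to tone + session-mean reaction time for Miss/CR,
#' which have no lick) and time-warped to `target_len` points.  Each cell
#' is rendered non-negative by subtracting its minimum and normalised by
#' the mean over Hit trials of the per-trial maxima; cells whose Hit maxima
#' are non-positive are excluded.  Cells are concatenated across sessions
#' along the neuron mode.
#'
#' @param sessions A `vip_session` or list of them.
#' @param trials_per_type Trials kept per outcome (default 10).
#' @param target_len Warped time points (default 30, spanning 1.5 s).
#' @return Object of class `vip_tensor`: `data` (N x T x K, non-negative),
#'   `trial_types` (length K), `cells` (data frame session/neuron),
#'   `offsets` and `norms` per cell.
#' @export
build_tensor <- function(sessions, trials_per_type = 10, target_len = 30) {
  if (inherits(sessions, "vip_session")) sessions <- list(sessions)
  type_order <- c("Hit", "FA", "Miss", "CR")
  slabs <- list(); cells <- list(); offsets <- c(); norms <- c()
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    counts <- table(factor(ses$trials$type, levels = type_order))
    if (any(counts < trials_per_type)) {
      message("session ", s, " excluded: fewer than ", trials_per_type,
              " trials of some type")
      next
    }
    dff <- compute_dff(ses)
    fs <- ses$sample_rate
    reinforced <- ses$trials$type %in% c("Hit", "FA")
    mean_rt <- mean(ses$trials$reaction_time[reinforced])
    seg_for <- function(j) {
      t0 <- ses$trials$tone_onset[j]
      t1 <- if (reinforced[j]) ses$trials$reinforcement_onset[j] else
        t0 + mean_rt
      i0 <- floor(t0 * fs) + 1L
      i1 <- max(ceiling(t1 * fs) + 1L, i0 + 1L)
      i0:min(i1, ncol(dff$F))
    }
    trial_ids <- unlist(lapply(type_order, function(tt) {
      which(ses$trials$type == tt)[seq_len(trials_per_type)]
    }))
    n <- nrow(dff$F)
    W <- array(NA_real_, c(n, target_len, length(trial_ids)))
    for (jj in seq_along(trial_ids)) {
      idx <- seg_for(trial_ids[jj])
      for (i in seq_len(n)) {
        W[i, , jj] <- time_warp(dff$F[i, idx], target_len)
      }
    }
    ttypes <- rep(type_order, each = trials_per_type)
    hit_k <- which(ttypes == "Hit")
    for (i in seq_len(n)) {
      off <- min(W[i, , ])
      Wi <- W[i, , ] - off
      hit_max <- mean(apply(Wi[, hit_k, drop = FALSE], 2, max))
      if (hit_max <= 0) {
        message("cell ", i, " of session ", s,
                " excluded: non-positive Hit maxima")
        next
      }
      slabs[[length(slabs) + 1L]] <- Wi / hit_max
      cells[[length(cells) + 1L]] <- data.frame(session = s, neuron = i)
      offsets <- c(offsets, off); norms <- c(norms, hit_max)
    }
  }
  if (!length(slabs)) stop("no cells available to build a tensor")
  N <- length(slabs)
  data <- array(0, c(N, target_len, dim(slabs[[1]])[2]))
  for (i in seq_len(N)) data[i, , ] <- slabs[[i]]
  structure(list(data = data,
                 trial_types = rep(type_order, each = trials_per_type),
                 cells = do.call(rbind, cells), offsets = offsets,
                 norms = norms),
            class = "vip_tensor")
}

#' Non-negative CP (tensor component) decomposition
#'
#' Rank-`rank` canonical polyadic decomposition with non-negativity on all
#' three factor matrices, fitted by hierarchical alternating least squares
#' (HALS).  The best of `n_init` random initialisations (by relative
#' reconstruction error) is returned; deterministic given `seed`.
#'
#' @param dataset A [build_tensor()] result or a plain 3-way array.
#' @param rank Number of components (>= 1).
#' @param n_init Random restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter HALS iteration cap per restart (default 500).
#' @param tol Relative-error change tolerance for convergence.
#' @return Object of class `vip_factors`: `neuron` (N x r), `temporal`
#'   (T x r), `trial` (K x r), `rank`, `error` (relative Frobenius
#'   reconstruction error, in \[0, 1\]).
#' @export
nncp_decompose <- function(dataset, rank, n_init = 10, seed = 1,
                           max_iter = 500, tol = 1e-8) {
  X <- if (inherits(dataset, "vip_tensor")) dataset$data else dataset
  stopifnot(length(dim(X)) == 3, rank >= 1)
  if (all(X == 0)) stop("degenerate input: zero tensor")
  dims <- dim(X)
  X1 <- matrix(aperm(X, c(1, 2, 3)), dims[1], dims[2] * dims[3])
  X2 <- matrix(aperm(X, c(2, 1, 3)), dims[2], dims[1] * dims[3])
  X3 <- matrix(aperm(X, c(3, 1, 2)), dims[3], dims[1] * dims[2])
  normX <- sqrt(sum(X^2))
  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      A <- matrix(stats::runif(dims[1] * rank), dims[1], rank)
      B <- matrix(stats::runif(dims[2] * rank), dims[2], rank)
      C <- matrix(stats::runif(dims[3] * rank), dims[3], rank)
      err_prev <- Inf
      for (it in seq_len(max_iter)) {
        A <- hals_update(A, X1, B, C)
        B <- hals_update(B, X2, A, C)
        C <- hals_update(C, X3, A, B)
        err <- cp_rel_error(X1, A, B, C, normX)
        if (abs(err_prev - err) < tol) break
        err_prev <- err
      }
      if (is.null(best) || err < best$error) {
        best <- list(neuron = A, temporal = B, trial = C, error = err)
      }
    }
    structure(c(best, list(rank = rank, dims = dims)),
              class = "vip_factors")
  })
}

# Column-wise Khatri-Rao product.
khatri_rao <- function(B, C) {
  r <- ncol(B)
  out <- matrix(0, nrow(B) * nrow(C), r)
  for (j in seq_len(r)) out[, j] <- kronecker(B[, j], C[, j])
  out
}

# One HALS sweep over the columns of factor A for unfolding Xn, where the
# Khatri-Rao companion factors are (U, V) and Xn ~ A t(khatri_rao(V, U)).
hals_update <- function(A, Xn, U, V) {
  W <- Xn %*% khatri_rao(V, U)
  G <- crossprod(U) * crossprod(V)
  for (j in seq_len(ncol(A))) {
    gjj <- G[j, j]
    if (gjj < 1e-12) {
      A[, j] <- 0
      next
    }
    A[, j] <- pmax(0, A[, j] + (W[, j] - A %*% G[, j]) / gjj)
  }
  A
}

cp_rel_error <- function(X1, A, B, C, normX) {
  W <- X1 %*% khatri_rao(C, B)
  G <- crossprod(A) * crossprod(B) * crossprod(C)
  # ||X - Xhat||^2 = ||X||^2 - 2 <X1, A KR'> + sum(G)
  sq <- normX^2 - 2 * sum(W * A) + sum(G)
  sqrt(max(sq, 0)) / normX
}

#' Trial-factor separation between reinforced and unreinforced trials
#'
#' Two-sided Mann-Whitney test per component of the trial factors between
#' reinforced (Hit, FA) and unreinforced (Miss, CR) trials; the component
#' with the smallest p-value is reported as the reinforcement component.
#'
#' @param factors A [nncp_decompose()] result.
#' @param trial_types Trial type per tensor slice (length K).
#' @return List: `p_values` (per component), `reinforcement_component`,
#'   `group_means` (matrix components x {reinforced, unreinforced}).
#' @export
trial_factor_separation <- function(factors, trial_types) {
  Tr <- factors$trial
  stopifnot(nrow(Tr) == length(trial_types))
  if (length(trial_types) < 4) stop("need at least 4 trials")
  g1 <- trial_types %in% c("Hit", "FA")
  if (!any(g1) || all(g1)) stop("both trial groups must be present")
  p <- vapply(seq_len(ncol(Tr)), function(j) {
    stats::wilcox.test(Tr[g1, j], Tr[!g1, j], exact = FALSE)$p.value
  }, numeric(1))
  gm <- cbind(reinforced = colMeans(Tr[g1, , drop = FALSE]),
              unreinforced = colMeans(Tr[!g1, , drop = FALSE]))
  list(p_values = p, reinforcement_component = which.min(p),
       group_means = gm)
}
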