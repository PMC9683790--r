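# Aligned Hit responses for clustering tests come from cached default
# sessions restricted to reward responders (the population the clustering
# pipeline operates on).
reward_aligned <- function(seed, n_neurons = 150, n_trials = 96) {
  ses <- cached_session(paste0("clust", seed), n_neurons = n_neurons,
                        n_trials = n_trials, seed = seed)
  al <- align_trials(ses, mode = "expected_reinforcement", window = c(-2, 4))
  keep <- which(ses$truth$responds_reward)
  al$data <- al$data[keep, , , drop = FALSE]
  list(aligned = al, truth = ses$truth$archetype[keep])
}

test_that("preprocess_profiles z-scores, normalises and excludes degenerates", {
  fx <- reward_aligned(41)
  prof <- suppressMessages(preprocess_profiles(fx$aligned))
  time <- attr(prof, "time")
  wi <- which(time >= 0 & time < 4)
  # post-reward maximum amplitude is 1 after normalisation
  expect_equal(unname(apply(abs(prof[, wi]), 1, max)),
               rep(1, nrow(prof)))
  # affine invariance: scaling and shifting the dF/F leaves profiles intact
  al2 <- fx$aligned
  al2$data <- 3 * al2$data + 0.7
  prof2 <- suppressMessages(preprocess_profiles(al2))
  expect_equal(unclass(prof), unclass(prof2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # constant profile is excluded with a message
  al3 <- fx$aligned
  al3$data[2, , ] <- 5
  expect_message(prof3 <- preprocess_profiles(al3, outlier_factor = Inf),
                 "zero first-second SD")
  expect_false(2 %in% attr(prof3, "kept"))
})

test_that("pca_reduce retains the smallest count reaching the variance threshold", {
  # rank-1 data -> a single component
  set.seed(2)
  base <- sin(seq(0, 3, length.out = 50))
  X <- outer(rnorm(30, 1, 0.3), base)
  p1 <- pca_reduce(X, var_threshold = 0.9)
  expect_equal(p1$n_retained, 1)
  # 4 orthogonal archetype directions + small noise -> 4 components
  Q <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))
  S <- matrix(rnorm(200 * 4, sd = 1), 200, 4) %*% t(Q) +
    matrix(rnorm(200 * 50, sd = 0.05), 200, 50)
  p4 <- pca_reduce(S, var_threshold = 0.9)
  expect_equal(p4$n_retained, 4)
  # isotropic noise in d dimensions needs about 0.9 d components
  N <- matrix(rnorm(4000 * 20), 4000, 20)
  pn <- pca_reduce(N, var_threshold = 0.9)
  expect_true(abs(pn$n_retained - 18) <= 1)
  expect_error(pca_reduce(X[1, , drop = FALSE]), "2 profiles")
})

test_that("kmeans_cluster recovers separated blobs and is deterministic", {
  set.seed(3)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 18), 5, 2, byrow = TRUE)
  truth <- rep(1:5, each = 40)
  X <- centers[truth, ] + matrix(rnorm(400, sd = 0.5), 200, 2)
  cl <- kmeans_cluster(X, k = 5, seed = 1)
  expect_equal(ari(cl$labels, truth), 1)
  cl2 <- kmeans_cluster(X, k = 5, seed = 1)
  expect_identical(cl$labels, cl2$labels)
  # fewer distinct points than k -> error
  expect_error(kmeans_cluster(matrix(1, 10, 2), k = 5), "distinct")
})

test_that("archetype clustering recovers planted labels at default SNR", {
  fx <- reward_aligned(42)
  prof <- suppressMessages(preprocess_profiles(fx$aligned))
  pcs <- pca_reduce(prof)
  cl <- kmeans_cluster(pcs$scores, k = 5, seed = 42)
  expect_gte(ari(cl$labels, fx$truth[attr(prof, "kept")]), 0.9)
  # neuron-order invariance: permuting cells permutes labels consistently
  perm <- sample(nrow(prof))
  clp <- kmeans_cluster(pcs$scores[perm, ], k = 5, seed = 42)
  expect_equal(ari(clp$labels, cl$labels[perm]), 1)
})

test_that("clustering collapses when the archetype mix is concentrated", {
  ses <- generate_session(session_config(
    n_neurons = 100, n_trials = 64, seed = 43,
    archetype_mix = c(fast = 0.9, delayed = 0.025, sustained = 0.025,
                      biphasic = 0.025, slow = 0.025)))
  al <- align_trials(ses, mode = "expected_reinforcement", window = c(-2, 4))
  keep <- which(ses$truth$responds_reward)
  al$data <- al$data[keep, , , drop = FALSE]
  prof <- suppressMessages(preprocess_profiles(al))
  cl <- kmeans_cluster(pca_reduce(prof)$scores, k = 5, seed = 43)
  expect_gte(max(table(cl$labels)) / length(cl$labels), 0.8)
})

test_that("feature projection scores profiles against unit-norm features", {
  set.seed(4)
  F <- matrix(rnorm(5 * 40), 5, 40)
  Fu <- F / sqrt(rowSums(F^2))
  # profile equal to feature j -> maximal score 1 at j
  sc <- feature_projection(Fu, F)
  expect_equal(diag(sc), rep(1, 5))
  for (j in 1:5) expect_equal(which.max(abs(sc[j, ])), j)
  # orthogonal profile -> zero scores
  v <- rnorm(40)
  v <- v - t(Fu) %*% solve(Fu %*% t(Fu), Fu %*% v)  # project out features
  sc0 <- feature_projection(matrix(as.numeric(v), 1), F)
  expect_equal(as.numeric(sc0), rep(0, 5), tolerance = 1e-9)
})

test_that("area comparison detects planted fast/slow regional bias", {
  # planted bias: area A cells load on feature 1, area B on feature 2
  set.seed(5)
  n <- 100
  scores <- rbind(cbind(rnorm(n, 1), rnorm(n, 0)),
                  cbind(rnorm(n, 0), rnorm(n, 1)))
  areas <- rep(c("Pta", "V1"), each = n)
  cmp <- compare_by_area(scores, areas, "Pta", "V1")
  expect_lt(cmp$p_value[1], 0.001)
  expect_lt(cmp$p_value[2], 0.001)
  expect_gt(cmp$mean_diff[1], 0)
  expect_lt(cmp$mean_diff[2], 0)
  # identical distributions -> roughly uniform p over seeds
  ps <- replicate(40, {
    s2 <- matrix(rnorm(60), 30)
    compare_by_area(s2, rep(c("A", "B"), 15), "A", "B")$p_value[1]
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(compare_by_area(scores, rep("A", 200)), "two areas")
})

test_that("depth distributions are tested for homogeneity across clusters", {
  set.seed(6)
  labels <- rep(1:5, each = 40)
  # depth independent of label: p > 0.05 in most seeds
  ps <- replicate(30, {
    depth_distribution(labels, runif(200, 50, 350))$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)
  # one cluster 200 um deeper -> strongly significant
  depths <- runif(200, 50, 350)
  depths[labels == 3] <- depths[labels == 3] + 200
  expect_lt(depth_distribution(labels, depths)$p_value, 0.01)
  # single cluster: undefined sentinel
  expect_true(is.na(depth_distribution(rep(1, 10), runif(10))$p_value))
})

test_that("cue-response regression reports R2 and F-test p", {
  hit_rate <- seq(0.3, 0.95, length.out = 12)
  # perfectly linear -> R2 = 1
  fit <- suppressWarnings(regress_cue_response(hit_rate, 0.1 + 0.5 * hit_rate))
  expect_equal(fit$r_squared, 1)
  # constant response -> R2 = 0
  fit0 <- regress_cue_response(hit_rate, rep(0.4, 12))
  expect_equal(fit0$r_squared, 0)
  # planted slope with noise tuned to population R2 ~ 0.39 at n = 200
  set.seed(7)
  x <- runif(200, 0.3, 1)
  beta <- 0.5
  # R2 = b^2 var(x) / (b^2 var(x) + s^2); solve s for R2 = 0.39
  s <- sqrt(beta^2 * var(x) * (1 - 0.39) / 0.39)
  y <- beta * x + rnorm(200, 0, s)
  fitn <- regress_cue_response(x, y)
  expect_lt(abs(fitn$r_squared - 0.39), 0.05)
  # region dummy model on 4 categories
  region <- sample(c("Mtr", "SS", "Pta", "V1"), 40, replace = TRUE)
  yr <- rnorm(40)
  fr <- regress_cue_response(region, yr)
  expect_true(fr$r_squared >= 0 && fr$r_squared <= 1)
  # rank-deficient design -> error
  expect_error(regress_cue_response(rep(1, 10), rnorm(10)), "rank-deficient")
})
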