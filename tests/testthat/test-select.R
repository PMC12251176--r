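make_curves <- function(X, q = seq(0, 0.45, length.out = ncol(X))) {
  out <- lapply(seq_len(nrow(X)), function(i) sans_curve(q, X[i, ]))
  names(out) <- sprintf("c%02d", seq_len(nrow(X)))
  out
}

test_that("confidence filtering is inclusive at the cutoff and composable", {
  models <- lapply(c(70, 75, 80), function(s)
    bead_model(matrix(runif(9), 3), id = paste0("m", s), confidence = s))
  ens <- structure_ensemble(models)
  expect_length(filter_by_confidence(ens, 75)$models, 2L)
  expect_length(filter_by_confidence(ens, 0)$models, 3L)
  expect_error(filter_by_confidence(ens, 101), "\\[0, 100\\]")
  expect_error(filter_by_confidence(ens, 90), "no models")
  # filtering twice equals filtering at the larger cutoff
  f2 <- filter_by_confidence(filter_by_confidence(ens, 72), 78)
  expect_equal(tidy(f2), tidy(filter_by_confidence(ens, 78)))
})

test_that("PCA of a rank-1 curve family gives equally spaced PC1 scores", {
  set.seed(3)
  q <- seq(0, 0.45, length.out = 50)
  c0 <- exp(-q^2 * 40)
  v <- sin(8 * q) * 0.05
  curves <- make_curves(rbind(c0, c0 + v, c0 + 2 * v), q)
  emb <- pca_curves(curves)
  expect_equal(emb$n_components, 2L)
  expect_gt(emb$explained_variance_ratio[1], 0.999)
  a <- sqrt(sum(v^2))
  expect_equal(sort(emb$projections$PC1), c(-a, 0, a), tolerance = 1e-10)
  expect_equal(emb$mean_curve$I, c0 + v, tolerance = 1e-12)
  # sign convention: largest-magnitude PC1 loading is positive
  expect_gt(emb$loadings[1, which.max(abs(emb$loadings[1, ]))], 0)
})

test_that("identical curves make the embedding degenerate", {
  q <- seq(0, 0.45, length.out = 20)
  curves <- make_curves(matrix(rep(exp(-q), 4), 4, byrow = TRUE), q)
  expect_error(pca_curves(curves), "degenerate")
})

test_that("PC1 separates two planted curve clusters and labels follow PC1", {
  set.seed(9)
  q <- seq(0, 0.45, length.out = 60)
  base1 <- exp(-q^2 * 30); base2 <- exp(-q^2 * 55)
  X <- rbind(t(replicate(10, base1 + rnorm(60, 0, 1e-4))),
             t(replicate(10, base2 + rnorm(60, 0, 1e-4))))
  emb <- pca_curves(make_curves(X, q))
  side <- emb$projections$PC1 > 0
  expect_true(all(side[1:10] == side[1]) && all(side[11:20] == side[11]) &&
                side[1] != side[11])
  labels <- cluster_embedding(emb, k = 2)
  expect_setequal(unique(labels), c(0L, 1L))
  pc1_means <- tapply(emb$projections$PC1, labels, mean)
  expect_lt(pc1_means[["0"]], pc1_means[["1"]])
})

test_that("well-separated pairs and planted gaussians cluster perfectly", {
  X <- cbind(c(-1, -1.1, 1, 1.1), 0)
  expect_equal(cluster_embedding(X, 2), c(0L, 0L, 1L, 1L))
  expect_error(cluster_embedding(X, 5), "fewer points")
  set.seed(4)
  pts <- cbind(c(rnorm(25, -1, 0.05), rnorm(25, 1, 0.05)), rnorm(50, 0, 0.05))
  labs <- cluster_embedding(pts, 2)
  expect_equal(labs, rep(c(0L, 1L), each = 25))
})

test_that("mean silhouette matches hand computation and brute-force oracle", {
  X1 <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab1 <- c(0, 0, 1, 1)
  s <- mean_silhouette(X1, lab1)
  expect_equal(s, silhouette_brute(X1, lab1), tolerance = 1e-15)
  expect_equal(s, 0.99, tolerance = 1e-3)
  # coincident clusters (same two positions in each): no separation
  X2 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_lte(mean_silhouette(X2, c(0, 0, 1, 1)), 0)
  expect_error(mean_silhouette(X1, c(0, 0, 0, 0)), "2 clusters")
  # random instances against the oracle and against cluster::silhouette
  set.seed(12)
  for (i in 1:50) {
    X <- matrix(rnorm(40), ncol = 2)
    lab <- sample(0:2, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ours <- mean_silhouette(X, lab)
    expect_equal(ours, silhouette_brute(X, lab), tolerance = 1e-12)
    if (all(table(lab) > 1)) {
      ref <- mean(cluster::silhouette(lab, stats::dist(X))[, "sil_width"])
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("threshold sweep finds a cutoff excluding planted intermediates", {
  fx <- make_two_state_ensemble(fixture_spec(seed = 42))
  curves <- batch_curves(fx$ensemble, norm_opts())
  sw <- threshold_sweep(fx$ensemble, curves)
  expect_gt(sw$best_threshold, 80)
  sil_at_base <- sw$sweep$silhouette[sw$sweep$threshold == 75]
  expect_gt(sw$best_silhouette, sil_at_base)
  # retained-model counts never increase along the sweep
  expect_true(all(diff(sw$sweep$n_retained) <= 0))
  # no intermediate survives the chosen cutoff
  truth <- fx$truth[match(sw$labels$model_id, fx$truth$model_id), ]
  expect_false(any(truth$state == "intermediate"))
  # clusters recover the planted states
  purity <- mean(vapply(split(truth$state, sw$labels$label),
                        function(s) max(table(s)) / length(s), 0))
  expect_gte(purity, 0.95)
  # representatives have maximal confidence within their cluster
  for (l in sw$representatives$label) {
    in_cl <- sw$labels[sw$labels$label == l, ]
    expect_equal(sw$representatives$mean_confidence[sw$representatives$label == l],
                 max(in_cl$mean_confidence))
  }
})

test_that("sweep results are invariant to model ordering", {
  fx <- make_two_state_ensemble(fixture_spec(seed = 7, n_models_per_state = 8,
                                             n_intermediates = 3))
  curves <- batch_curves(fx$ensemble, norm_opts())
  sw1 <- threshold_sweep(fx$ensemble, curves)
  set.seed(1)
  perm <- sample(length(fx$ensemble$models))
  ens2 <- structure_ensemble(fx$ensemble$models[perm])
  sw2 <- threshold_sweep(ens2, curves[perm])
  expect_equal(sw1$sweep, sw2$sweep)
  expect_equal(sw1$best_threshold, sw2$best_threshold)
  expect_equal(sort(sw1$representatives$model_id),
               sort(sw2$representatives$model_id))
})

test_that("a single-blob ensemble scores a low silhouette and warns", {
  # one featureless cloud: a base curve plus several comparable random modes,
  # with near-tied confidences so every threshold retains many models
  set.seed(13)
  q <- seq(0, 0.45, length.out = 60)
  c0 <- exp(-q^2 * 40)
  modes <- svd(matrix(rnorm(60 * 4), 60, 4))$u * 0.02
  n <- 20
  X <- t(replicate(n, c0 + as.vector(modes %*% rnorm(4))))
  curves <- make_curves(X, q)
  conf <- c(rep(85, n - 2), 88, 88.5)
  models <- lapply(seq_len(n), function(i)
    bead_model(matrix(runif(9), 3), id = names(curves)[i], confidence = conf[i]))
  ens <- structure_ensemble(models)
  sw <- threshold_sweep(ens, curves)
  expect_lt(sw$best_silhouette, 0.5)
})

test_that("state discovery warns when cluster separation is poor", {
  fx <- make_two_state_ensemble(fixture_spec(seed = 2, n_models_per_state = 6,
                                             n_intermediates = 0))
  expect_warning(run_state_discovery(fx$ensemble, norm_opts(),
                                     silhouette_floor = 0.999),
                 "poorly separated")
})

test_that("explicit single-threshold sweeps and degenerate cases behave", {
  fx <- make_two_state_ensemble(fixture_spec(seed = 5, n_models_per_state = 5,
                                             n_intermediates = 0))
  curves <- batch_curves(fx$ensemble, norm_opts())
  sw <- threshold_sweep(fx$ensemble, curves, thresholds = 75)
  expect_equal(nrow(sw$sweep), 1L)
  expect_equal(sw$best_threshold, 75)
  # thresholds retaining < 3 models are recorded as NA and skipped
  hi <- max(tidy(fx$ensemble)$mean_confidence)
  sw2 <- threshold_sweep(fx$ensemble, curves, thresholds = c(75, hi))
  expect_true(is.na(sw2$sweep$silhouette[2]))
  expect_equal(sw2$best_threshold, 75)
  expect_error(threshold_sweep(fx$ensemble, curves, thresholds = hi),
               "no threshold")
})

test_that("representatives come one from each planted state across seeds", {
  hits <- 0L
  n_seed <- 20L
  for (seed in seq_len(n_seed)) {
    fx <- make_two_state_ensemble(fixture_spec(seed = seed))
    curves <- batch_curves(fx$ensemble, norm_opts())
    sw <- threshold_sweep(fx$ensemble, curves)
    states <- fx$truth$state[match(sw$representatives$model_id,
                                   fx$truth$model_id)]
    if (setequal(states, c("state1", "state2"))) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.95)
})
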