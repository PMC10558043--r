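# Shared small planted world for the classifier tests: 4 clusters, 40
# pairs, planted signals; scored with few permutations (labels only need to
# be consistent, not calibrated, for these tests).
classifier_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- build_classifier_world()
    cache
  }
})

build_classifier_world <- function() {
  db <- make_toy_lridb(40, multi_subunit_frac = 0.2, seed = 15)
  planted <- withr::with_seed(16, data.frame(
    source = sample(4, 14, replace = TRUE),
    target = sample(4, 14, replace = TRUE),
    pair = sample(40, 14)
  ))
  spec <- synthetic_spec(n_cells = 240, n_genes = 220, n_clusters = 4,
                         markers_per_cluster = 8, lridb = db,
                         planted_ccis = planted, lr_effect = 8, seed = 17)
  sim <- simulate_counts(spec)
  Xn <- normalize_log(qc_filter(sim$X))
  db_f <- filter_pairs_to_genes(db, rownames(Xn))
  tensor <- label_significant(Xn, sim$labels, db_f, n_perm = 200, seed = 18)
  graph <- build_lr_pair_graph(tensor, top_n = 40, tau = 0.95)
  list(db = db_f, sim = sim, Xn = Xn, tensor = tensor, graph = graph)
}

test_that("focal loss matches hand values and reduces to cross-entropy", {
  expect_equal(focal_loss(1, 0.9, gamma = 2), 0.01 * (-log(0.9)))
  expect_equal(round(focal_loss(1, 0.9, gamma = 2), 7), 0.0010536)
  expect_lt(focal_loss(1, 1 - 1e-7, gamma = 2), 1e-13)
  bce <- function(y, p) mean(-(y * log(p) + (1 - y) * log(1 - p)))
  yp <- withr::with_seed(3, cbind(rbinom(1000, 1, 0.4), runif(1000, 0.01, 0.99)))
  expect_lt(abs(focal_loss(yp[, 1], yp[, 2], gamma = 0) - bce(yp[, 1], yp[, 2])),
            1e-10)
  # monotonicity on a grid
  grid <- seq(0.01, 0.99, by = 0.01)
  l1 <- vapply(grid, function(p) focal_loss(1, p, 2), 0)
  l0 <- vapply(grid, function(p) focal_loss(0, p, 2), 0)
  expect_true(all(diff(l1) <= 0))
  expect_true(all(diff(l0) >= 0))
  expect_error(focal_loss(1, 0.5, gamma = -1), "gamma")
})

test_that("SVD feature reduction is exact at full rank and stable", {
  B <- withr::with_seed(5, outer(rnorm(8), rnorm(6)))  # rank 1
  red <- cellcrosstalk:::svd_reduce(B, 1)
  v1 <- svd(B)$v[, 1]
  v1 <- v1 * sign(v1[which.max(abs(v1))])
  expect_equal(red %*% t(v1), B, tolerance = 1e-6, ignore_attr = TRUE)
  # permuting cells (columns) leaves singular values unchanged
  B2 <- withr::with_seed(6, matrix(rnorm(48), 8, 6))
  r_a <- cellcrosstalk:::svd_reduce(B2, 3)
  r_b <- cellcrosstalk:::svd_reduce(B2[, sample(6)], 3)
  expect_equal(sqrt(colSums(r_a^2)), sqrt(colSums(r_b^2)), tolerance = 1e-8)
  expect_equal(sqrt(colSums(r_a^2)), svd(B2)$d[1:3], tolerance = 1e-8)
  # fewer cells than d: zero padding
  r_pad <- cellcrosstalk:::svd_reduce(B2, 10)
  expect_equal(dim(r_pad), c(8, 10))
  expect_true(all(r_pad[, 7:10] == 0))
})

test_that("feature samples carry per-cell complex expression and labels", {
  w <- classifier_world()
  feats <- build_cci_features(w$Xn, w$sim$labels, w$db, w$tensor,
                              nodes = w$graph$nodes, d = 8)
  K <- length(w$tensor$clusters)
  expect_length(feats$samples, K * K)
  s <- feats$samples[[2]]  # source 1, target 2
  expect_equal(dim(s$features), c(length(w$graph$nodes), 16))
  expect_identical(s$y, as.integer(w$tensor$significant[1, 2, w$graph$nodes]))
  # a ligand with a zero subunit in every source cell gives a zero row block
  Xz <- w$Xn
  p1 <- w$db$pairs[[w$graph$nodes[1]]]
  Xz[p1$ligand[1], w$sim$labels == 1] <- 0
  fz <- build_cci_features(Xz, w$sim$labels, w$db, w$tensor,
                           nodes = w$graph$nodes, d = 8)
  # zero up to SVD floating-point noise on the rank-deficient block
  expect_lt(max(abs(fz$samples[[2]]$features[1, 1:8])), 1e-8)
  expect_error(
    build_cci_features(w$Xn, replace(w$sim$labels, w$sim$labels == 2, 1)[
      seq_along(w$sim$labels)], w$db, w$tensor, d = 4),
    "fewer than 2 cells"
  )
})

test_that("forward pass respects output contracts", {
  w <- classifier_world()
  n_pairs <- length(w$graph$nodes)
  feats <- build_cci_features(w$Xn, w$sim$labels, w$db, w$tensor,
                              nodes = w$graph$nodes, d = 8)
  params <- interaction_model_init(n_pairs, 16, w$graph, width = 16L,
                                   emb_dim = 8L, seed = 2)
  prob <- predict_sample(feats$samples[[3]]$features, w$graph, params)
  expect_length(prob, n_pairs)
  expect_true(all(prob > 0 & prob < 1))
  # purity: identical inputs give identical outputs
  expect_identical(prob, predict_sample(feats$samples[[3]]$features,
                                        w$graph, params))
  # zero final layer: sigmoid(0) = 0.5 everywhere
  params0 <- params
  params0$Wfc[] <- 0; params0$b_fc[] <- 0
  expect_equal(predict_sample(feats$samples[[3]]$features, w$graph, params0),
               rep(0.5, n_pairs))
  expect_error(predict_sample(feats$samples[[3]]$features[1:5, ], w$graph,
                              params), "pair count")
})

test_that("a planted linear rule is learned to near-oracle accuracy", {
  # labels determined by one feature column; logistic regression attains
  # AUC 1 on this world, and the network should come close under CV
  set.seed(2)
  n_pairs <- 30; d <- 4; K <- 6
  arr <- array(abs(rnorm(K * K * n_pairs)), c(K, K, n_pairs))
  graph <- build_lr_pair_graph(arr, top_n = n_pairs, tau = 0.95)
  samples <- lapply(seq_len(K * K), function(s) {
    f <- matrix(rnorm(n_pairs * 2 * d), n_pairs, 2 * d)
    list(source = (s - 1) %/% K + 1, target = (s - 1) %% K + 1,
         features = f, y = as.integer(f[, 1] > 0.3))
  })
  feats <- structure(list(samples = samples, nodes = seq_len(n_pairs),
                          pair_names = sprintf("P%02d", 1:n_pairs), d = d,
                          clusters = 1:K), class = "cci_features")
  probs <- unlist(lapply(samples, function(s) s$features[, 1]))
  ys <- unlist(lapply(samples, function(s) s$y))
  expect_equal(roc_auc(probs, ys), 1)  # the oracle separates perfectly
  cv <- train_interaction_model(feats, graph, folds = 5, seed = 3,
                                epochs = 200, lr = 3e-3,
                                width = 32L, emb_dim = 8L)
  expect_gte(mean(cv$metrics$auc, na.rm = TRUE), 0.95)
})

test_that("training descends, reproduces, and beats chance on planted data", {
  w <- classifier_world()
  feats <- build_cci_features(w$Xn, w$sim$labels, w$db, w$tensor,
                              nodes = w$graph$nodes, d = 8)
  cv <- train_interaction_model(feats, w$graph, folds = 4, seed = 5,
                                epochs = 60, width = 32L, emb_dim = 8L)
  expect_equal(nrow(cv$metrics), 4)
  # training loss decreases
  h <- attr(cv$models[[1]], "loss_history")
  expect_lt(h[length(h)], h[1])
  # this world has only 16 cluster-pair samples, so no held-out accuracy
  # claim is made here; the calibrated recovery bound lives in the
  # linear-rule test above and in the acceptance suite
  # determinism: same seed, same folds and metrics
  cv2 <- train_interaction_model(feats, w$graph, folds = 4, seed = 5,
                                 epochs = 60, width = 32L, emb_dim = 8L)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$metrics, cv2$metrics)
  expect_error(train_interaction_model(feats, w$graph, folds = 100),
               "fewer samples")
})

test_that("prediction emits calls with a closed lower threshold", {
  w <- classifier_world()
  feats <- build_cci_features(w$Xn, w$sim$labels, w$db, w$tensor,
                              nodes = w$graph$nodes, d = 8)
  params <- interaction_model_init(length(w$graph$nodes), 16, w$graph,
                                   width = 16L, emb_dim = 8L, seed = 3)
  params$Wfc[] <- 0; params$b_fc[] <- 0   # all probabilities exactly 0.5
  preds <- predict_interactions(params, feats, threshold = 0.5)
  expect_true(all(preds$call == 1L))      # boundary counts as positive
  expect_equal(nrow(preds), length(feats$samples) * length(w$graph$nodes))
  expect_true(all(c("source_cluster", "target_cluster", "ligand", "receptor",
                    "probability", "call") %in% names(preds)))
})
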