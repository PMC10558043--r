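test_that("autoencoder forward pass honors shape and activation contracts", {
  X <- matrix(rnorm(12), 3, 4)
  p <- ae_params_init(4, dims = c(3L, 2L), seed = 1)
  out <- ae_forward(X, p)
  expect_length(out$H, 3L)
  expect_equal(dim(out$H[[3]]), c(3, 2))
  expect_equal(dim(out$Xhat), dim(X))
  # all-zero weights and ReLU: every representation collapses to zero
  p0 <- p
  for (l in seq_along(p0$encoder)) {
    p0$encoder[[l]]$W[] <- 0; p0$encoder[[l]]$b[] <- 0
  }
  out0 <- ae_forward(X, p0)
  expect_true(all(out0$H[[2]] == 0))
  expect_true(all(out0$H[[3]] == 0))
  # identity-sized linear layers with identity weights reproduce the input
  pid <- ae_params_init(2, dims = c(2L), seed = 1)
  pid$encoder[[1]]$W <- diag(2); pid$encoder[[1]]$b[] <- 0
  pid$decoder[[1]]$W <- diag(2); pid$decoder[[1]]$b[] <- 0
  Xs <- matrix(rnorm(6), 3, 2)
  expect_equal(ae_forward(Xs, pid)$Xhat, Xs)
  expect_error(ae_forward(matrix(0, 2, 5), p), "expects")
  # determinism of initialization under one seed
  expect_identical(ae_params_init(4, c(3L, 2L), seed = 9),
                   ae_params_init(4, c(3L, 2L), seed = 9))
})

test_that("reconstruction loss is the halved mean Frobenius error", {
  X <- matrix(c(1, 0), 1, 2)
  expect_equal(reconstruction_loss(X, matrix(0, 1, 2)), 0.5)
  expect_equal(reconstruction_loss(X, X), 0)
  for (s in 1:5) {
    A <- withr::with_seed(s, matrix(rnorm(20), 4, 5))
    B <- withr::with_seed(s + 9, matrix(rnorm(20), 4, 5))
    expect_gte(reconstruction_loss(A, B), 0)
  }
  expect_error(reconstruction_loss(X, matrix(0, 2, 2)), "identical shapes")
})

test_that("representation fusion and GCN layer follow their formulas", {
  Z <- matrix(2, 1, 1); H <- matrix(4, 1, 1)
  expect_equal(combine_representations(Z, H, 0), Z)
  expect_equal(combine_representations(Z, H, 1), H)
  expect_equal(combine_representations(Z, H, 0.5), matrix(3, 1, 1))
  # identity adjacency and weights: layer is the identity map
  Zin <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(gcn_layer(Zin, diag(3), diag(2), identity), Zin)
  # complete two-node graph smooths equal rows to equal rows
  An <- as.matrix(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)))
  Zc <- matrix(c(1, 1, 2, 2), 2, 2)
  out <- gcn_layer(Zc, An, diag(2))
  expect_equal(out[1, ], out[2, ])
  # single node reduces to an activated affine map
  expect_equal(gcn_layer(matrix(3, 1, 1), matrix(1, 1, 1), matrix(2, 1, 1)),
               matrix(6, 1, 1))
})

test_that("soft assignment matches the Student's-t kernel", {
  # 1-D, h = 0, centers 0 and 1, v = 1: kernels 1 and 0.5
  Q <- soft_assign(matrix(0, 1, 1), matrix(c(0, 1), 2, 1), v = 1)
  expect_equal(Q[1, ], c(2 / 3, 1 / 3))
  # equidistant point splits evenly
  Q2 <- soft_assign(matrix(c(0.5, 0), 1, 2), matrix(c(0, 1, 0, 0), 2, 2), v = 1)
  expect_equal(Q2[1, ], c(0.5, 0.5))
  # rows sum to one for random inputs
  H <- matrix(rnorm(40), 10, 4)
  centers <- matrix(rnorm(12), 3, 4)
  expect_equal(rowSums(soft_assign(H, centers)), rep(1, 10))
  expect_true(all(soft_assign(H, centers) > 0))
  # all-equal centers yield uniform rows
  same <- matrix(1, 2, 4)
  expect_equal(soft_assign(H, same)[, 1], rep(0.5, 10))
})

test_that("target distribution sharpens and fixes its fixed points", {
  Q <- matrix(c(0.9, 0.1, 0.6, 0.4), 2, 2, byrow = TRUE)
  P <- target_distribution(Q)
  expect_equal(P, matrix(c(27 / 28, 1 / 28, 3 / 7, 4 / 7), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(round(P[1, ], 4), c(0.9643, 0.0357))
  expect_equal(round(P[2, ], 4), c(0.4286, 0.5714))
  # uniform and one-hot assignments are fixed points
  U <- matrix(1 / 3, 4, 3)
  expect_equal(target_distribution(U), U)
  hot <- diag(3)
  expect_equal(target_distribution(hot), hot)
  # sharpening: with equal frequencies, the max grows
  Qe <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE)
  Pe <- target_distribution(Qe)
  expect_true(all(apply(Pe, 1, max) >= apply(Qe, 1, max)))
  expect_warning(target_distribution(cbind(c(1, 1), c(0, 0))), "zero")
})

test_that("KL loss is zero iff equal and positive otherwise", {
  P <- matrix(c(0.7, 0.3), 1)
  expect_equal(kl_loss(P, P), 0)
  expect_equal(kl_loss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2))
  for (s in 1:10) {
    Q <- withr::with_seed(s, {
      m <- matrix(runif(12), 3, 4); m / rowSums(m)
    })
    Pm <- withr::with_seed(s + 20, {
      m <- matrix(runif(12), 3, 4); m / rowSums(m)
    })
    expect_gte(kl_loss(Pm, Q), 0)
  }
  expect_gt(kl_loss(matrix(c(0.9, 0.1), 1), matrix(c(0.1, 0.9), 1)), 0)
})

test_that("total loss combines components with the published weights", {
  w <- loss_weights()
  expect_equal(w$alpha, 1e-4)
  expect_equal(w$beta, 1e-3)
  expect_equal(total_loss(7, 9, 2, loss_weights(0, 0)), 2)
  expect_equal(total_loss(10, 20, 3, w), 1e-4 * 10 + 1e-3 * 20 + 3)
  expect_equal(total_loss(0, 0, 0, w), 0)
  expect_error(total_loss(Inf, 0, 0, w), "finite")
  expect_error(loss_weights(epsilon = 2), "epsilon")
})

test_that("pretraining descends, reproduces under a seed, and fits rank-1 data", {
  X <- withr::with_seed(1, {
    u <- rnorm(30); v <- rnorm(6)
    outer(u, v)  # rank-1: a 1-D embedding can represent it exactly
  })
  p1 <- pretrain_ae(X, dims = c(4L, 1L), epochs = 200L, seed = 3, lr = 1e-2)
  h <- attr(p1, "loss_history")
  expect_lt(h[length(h)], h[1])
  expect_lt(h[length(h)], 0.1 * h[1])
  p2 <- pretrain_ae(X, dims = c(4L, 1L), epochs = 200L, seed = 3, lr = 1e-2)
  attr(p1, "loss_history") <- NULL; attr(p2, "loss_history") <- NULL
  expect_identical(p1, p2)
})

test_that("joint clustering recovers planted structure deterministically", {
  spec <- synthetic_spec(n_cells = 150, n_genes = 80, n_clusters = 3,
                         de_strength = 8, markers_per_cluster = 20, seed = 21)
  sim <- simulate_counts(spec)
  Xh <- select_hvg(normalize_log(qc_filter(sim$X)), 80)
  pc <- stats::prcomp(t(Xh), rank. = 20)$x
  graph <- build_knn_graph(pc, K = 10)
  fit <- fit_cluster_model(Xh, graph, n_clusters = 3, seed = 7,
                           dims = c(32L, 8L), pretrain_epochs = 200L,
                           epochs = 30L)
  expect_gte(adjusted_rand_index(fit$labels, sim$labels), 0.9)
  # Q stays row-stochastic and strictly positive
  expect_equal(unname(rowSums(fit$Q)), rep(1, ncol(Xh)), tolerance = 1e-6)
  expect_true(all(fit$Q > 0))
  # labels are the argmax of Q
  expect_identical(fit$labels, max.col(fit$Q, ties.method = "first"))
  # determinism: the same seed reproduces labels exactly
  fit2 <- fit_cluster_model(Xh, graph, n_clusters = 3, seed = 7,
                            dims = c(32L, 8L), pretrain_epochs = 200L,
                            epochs = 30L)
  expect_identical(fit$labels, fit2$labels)
  expect_equal(fit$Q, fit2$Q)
})

test_that("disabling the GCN branch degenerates to AE-only deep clustering", {
  spec <- synthetic_spec(n_cells = 90, n_genes = 40, n_clusters = 2,
                         de_strength = 8, markers_per_cluster = 15, seed = 31)
  sim <- simulate_counts(spec)
  Xh <- normalize_log(sim$X)
  graph <- build_knn_graph(t(Xh), K = 5)
  fit <- fit_cluster_model(Xh, graph, n_clusters = 2,
                           weights = loss_weights(alpha = 1e-4, beta = 0,
                                                  epsilon = 1),
                           seed = 2, dims = c(16L, 4L),
                           pretrain_epochs = 150L, epochs = 20L)
  expect_equal(unname(rowSums(fit$Q)), rep(1, ncol(Xh)), tolerance = 1e-6)
  expect_equal(sort(unique(fit$labels)), 1:2)
})
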