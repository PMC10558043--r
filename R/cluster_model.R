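# Joint autoencoder + graph-convolution clustering.
#
# The network couples a fully connected autoencoder (reconstruction loss)
# with a GCN over the cell KNN graph, fusing the two branch representations
# layer by layer. Cluster membership is a Student's-t soft assignment Q
# around trainable centers; a sharpened target distribution P supervises
# both Q (KL) and the GCN's softmax assignment Z (KL). All gradients are
# derived analytically and optimised with full-batch Adam; everything is a
# pure function of the user seed.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Loss weights for the cluster model
#'
#' @param alpha Weight of the assignment KL term (default 1e-4).
#' @param beta Weight of the GCN KL term (default 1e-3).
#' @param epsilon Autoencoder share in the layerwise fusion (default 0.5).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1e-4, beta = 1e-3, epsilon = 0.5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "loss_weights")
}

#' Initialize autoencoder parameters
#'
#' Encoder layer widths default to 512, 256, 64 with a mirrored decoder;
#' hidden activations are ReLU, the embedding and output layers linear.
#'
#' @param input_dim Number of input features.
#' @param dims Encoder layer widths; the last entry is the embedding
#'   dimension.
#' @param seed Integer seed for Glorot-uniform initialization.
#' @return A list with `encoder` and `decoder` weight/bias lists and `dims`.
#' @export
ae_params_init <- function(input_dim, dims = c(512L, 256L, 64L), seed = 1L) {
  with_seed(seed, {
    enc_dims <- c(input_dim, dims)
    dec_dims <- rev(enc_dims)
    make <- function(d) {
      lapply(seq_len(length(d) - 1L), function(l) {
        list(W = glorot(d[l], d[l + 1L]), b = rep(0, d[l + 1L]))
      })
    }
    list(encoder = make(enc_dims), decoder = make(dec_dims),
         dims = as.integer(dims), input_dim = as.integer(input_dim))
  })
}

# Full forward pass with caches needed for backprop.
ae_forward_full <- function(X, params) {
  L <- length(params$encoder)
  H <- vector("list", L + 1L)
  pre_e <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    pre <- sweep(H[[l]] %*% params$encoder[[l]]$W, 2L,
                 params$encoder[[l]]$b, "+")
    pre_e[[l]] <- pre
    H[[l + 1L]] <- if (l < L) relu(pre) else pre
  }
  Ld <- length(params$decoder)
  D <- vector("list", Ld + 1L)
  pre_d <- vector("list", Ld)
  D[[1L]] <- H[[L + 1L]]
  for (l in seq_len(Ld)) {
    pre <- sweep(D[[l]] %*% params$decoder[[l]]$W, 2L,
                 params$decoder[[l]]$b, "+")
    pre_d[[l]] <- pre
    D[[l + 1L]] <- if (l < Ld) relu(pre) else pre
  }
  list(H = H, D = D, pre_e = pre_e, pre_d = pre_d, Xhat = D[[Ld + 1L]])
}

#' Autoencoder forward pass
#'
#' @param X Cells x features matrix (`H(0)`).
#' @param params Parameters from [ae_params_init()] or [pretrain_ae()].
#' @return A list with `H` (layer representations, `H[[1]]` being the input
#'   and the last entry the embedding) and `Xhat` (the reconstruction).
#' @export
ae_forward <- function(X, params) {
  stopifnot_matrix(X, "X")
  if (ncol(X) != params$input_dim) {
    stop(sprintf("X has %d features but the encoder expects %d",
                 ncol(X), params$input_dim), call. = FALSE)
  }
  f <- ae_forward_full(X, params)
  list(H = f$H, Xhat = f$Xhat)
}

#' Autoencoder reconstruction loss
#'
#' Mean squared Frobenius error, \eqn{\frac{1}{2N}\lVert X-\hat X\rVert_F^2}
#' with `N` the number of cells (rows).
#'
#' @param X,Xhat Matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, Xhat) {
  if (!identical(dim(X), dim(Xhat))) {
    stop("X and Xhat must have identical shapes", call. = FALSE)
  }
  sum((X - Xhat)^2) / (2 * nrow(X))
}

#' Fuse GCN and autoencoder representations
#'
#' \eqn{(1-\varepsilon) Z + \varepsilon H}; the fusion coefficient balances
#' graph-propagated against reconstruction-driven features.
#'
#' @param Z,H Same-shape matrices.
#' @param epsilon Fusion coefficient in `[0, 1]` (default 0.5).
#' @return Fused matrix.
#' @export
combine_representations <- function(Z, H, epsilon = 0.5) {
  if (!identical(dim(Z), dim(H))) {
    stop("Z and H must have identical shapes", call. = FALSE)
  }
  (1 - epsilon) * Z + epsilon * H
}

#' One graph-convolution layer
#'
#' @param Z_prev Input representation (nodes x d).
#' @param A_norm Normalized adjacency from [normalize_adjacency()].
#' @param W Weight matrix (d x d_out).
#' @param activation Elementwise activation (default ReLU).
#' @return Activated propagated representation.
#' @export
gcn_layer <- function(Z_prev, A_norm, W, activation = relu) {
  activation(as.matrix(A_norm %*% Z_prev %*% W))
}

student_t_kernel <- function(H, centers, v = 1) {
  d2 <- outer(rowSums(H^2), rowSums(centers^2), "+") -
    2 * H %*% t(centers)
  d2[d2 < 0] <- 0
  (1 + d2 / v)^(-(v + 1) / 2)
}

#' Student's-t soft cluster assignment
#'
#' \deqn{q_{ij} = \frac{(1+\lVert h_i-\mu_j\rVert^2/v)^{-(v+1)/2}}
#'   {\sum_{j'}(1+\lVert h_i-\mu_{j'}\rVert^2/v)^{-(v+1)/2}}}
#'
#' @param H Cells x d embedding.
#' @param centers Clusters x d center matrix.
#' @param v Degrees of freedom (default 1).
#' @return Row-stochastic cells x clusters matrix Q.
#' @export
soft_assign <- function(H, centers, v = 1) {
  stopifnot_matrix(H, "H")
  stopifnot_matrix(centers, "centers")
  if (ncol(H) != ncol(centers)) {
    stop("embedding and centers dimensions differ", call. = FALSE)
  }
  k <- student_t_kernel(H, centers, v)
  k / rowSums(k)
}

#' Self-training target distribution
#'
#' Squares and frequency-normalizes the soft assignment so high-confidence
#' assignments are sharpened:
#' \deqn{p_{ij} = \frac{q_{ij}^2/f_j}{\sum_{j'} q_{ij'}^2/f_{j'}},\quad
#'   f_j = \sum_i q_{ij}.}
#'
#' @param Q Row-stochastic soft assignment.
#' @return Row-stochastic target matrix P of the same shape.
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  if (any(f == 0)) {
    warning("soft cluster frequency is zero for some column(s); they are excluded",
            call. = FALSE)
    f[f == 0] <- Inf  # numerator becomes 0 for those columns
  }
  num <- sweep(Q^2, 2L, f, "/")
  num / rowSums(num)
}

#' Kullback-Leibler divergence between row-stochastic matrices
#'
#' \eqn{\sum_i\sum_j p_{ij}\log(p_{ij}/q_{ij})}, with `Q` clamped below at
#' `floor` so zero assignments cannot produce infinities.
#'
#' @param P,Q Same-shape row-stochastic matrices.
#' @param floor Numerical floor inside the logarithm (default 1e-12).
#' @return Non-negative scalar.
#' @export
kl_loss <- function(P, Q, floor = 1e-12) {
  if (!identical(dim(P), dim(Q))) {
    stop("P and Q must have identical shapes", call. = FALSE)
  }
  if (any(Q < floor & P > 0)) {
    message("kl_loss: assignment entries clamped at the numerical floor")
  }
  Qc <- pmax(Q, floor)
  pos <- P > 0
  sum(P[pos] * (log(P[pos]) - log(Qc[pos])))
}

#' Combined cluster-model loss
#'
#' \eqn{\alpha L_{clu} + \beta L_{gcn} + L_{res}}.
#'
#' @param l_clu,l_gcn,l_res Component losses.
#' @param weights A [loss_weights()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(l_clu, l_gcn, l_res, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  if (!all(is.finite(c(l_clu, l_gcn, l_res)))) {
    stop("component losses must be finite", call. = FALSE)
  }
  weights$alpha * l_clu + weights$beta * l_gcn + l_res
}

# ---- Adam over arbitrary nested parameter lists ----------------------------

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

adam_step <- function(params, grads, m, v, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g^2
    mh <- m2 / (1 - b1^t)
    vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
  walk(params, grads, m, v)
}

# Backprop of the reconstruction loss through the AE given forward caches;
# returns gradients plus the upstream gradient flowing into the embedding.
ae_backward <- function(X, params, fwd, dH_extra = NULL) {
  L <- length(params$encoder)
  Ld <- length(params$decoder)
  N <- nrow(X)
  g_enc <- lapply(params$encoder, function(p) list(W = p$W * 0, b = p$b * 0))
  g_dec <- lapply(params$decoder, function(p) list(W = p$W * 0, b = p$b * 0))
  dD <- (fwd$Xhat - X) / N
  for (l in Ld:1) {
    dpre <- if (l < Ld) dD * (fwd$pre_d[[l]] > 0) else dD
    g_dec[[l]]$W <- t(fwd$D[[l]]) %*% dpre
    g_dec[[l]]$b <- colSums(dpre)
    dD <- dpre %*% t(params$decoder[[l]]$W)
  }
  # dD now carries dLres/dH_embedding; add any external embedding gradient
  dH <- dD
  if (!is.null(dH_extra)) dH <- dH + dH_extra[[L + 1L]]
  for (l in L:1) {
    dpre <- if (l < L) dH * (fwd$pre_e[[l]] > 0) else dH
    g_enc[[l]]$W <- t(fwd$H[[l]]) %*% dpre
    g_enc[[l]]$b <- colSums(dpre)
    dH <- dpre %*% t(params$encoder[[l]]$W)
    if (!is.null(dH_extra) && l >= 2L) dH <- dH + dH_extra[[l]]
  }
  list(encoder = g_enc, decoder = g_dec)
}

#' Pretrain the autoencoder on reconstruction loss alone
#'
#' Full-batch Adam on \eqn{L_{res}}; a required step before joint training,
#' giving the embedding and the k-means initialization a sensible starting
#' point.
#'
#' @param X Cells x features matrix (preprocessed, variable genes selected).
#' @param dims Encoder widths (default `c(512, 256, 64)`).
#' @param epochs Training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed.
#' @param verbose Print loss every 50 epochs.
#' @return Trained parameters (as from [ae_params_init()]), with a
#'   `loss_history` attribute.
#' @export
pretrain_ae <- function(X, dims = c(512L, 256L, 64L), epochs = 200L,
                        lr = 1e-3, seed = 1L, verbose = FALSE) {
  stopifnot_matrix(X, "X")
  params <- ae_params_init(ncol(X), dims, seed = derive_seed(seed, "ae-init"))
  core <- list(encoder = params$encoder, decoder = params$decoder)
  m <- zeros_like(core); v <- zeros_like(core)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- ae_forward_full(X, params)
    loss <- reconstruction_loss(X, fwd$Xhat)
    if (!is.finite(loss)) {
      stop(sprintf("autoencoder diverged at epoch %d", ep), call. = FALSE)
    }
    history[ep] <- loss
    grads <- ae_backward(X, params, fwd)
    st <- adam_step(core, grads, m, v, lr, ep)
    core <- st$p; m <- st$m; v <- st$v
    params$encoder <- core$encoder; params$decoder <- core$decoder
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("pretrain epoch %d: Lres = %.6f", ep, loss))
    }
  }
  attr(params, "loss_history") <- history
  params
}

kmeans_init_centers <- function(H, n_clusters, seed, attempts = 10L) {
  for (a in seq_len(attempts)) {
    km <- try(with_seed(derive_seed(seed, paste0("kmeans", a)), {
      stats::kmeans(H, centers = n_clusters, nstart = 10L, iter.max = 100L)
    }), silent = TRUE)
    if (!inherits(km, "try-error") && all(km$size > 0)) return(km)
  }
  stop(sprintf("k-means produced an empty cluster in %d attempts", attempts),
       call. = FALSE)
}

#' Fit the joint autoencoder + GCN cluster model
#'
#' Pretrains the autoencoder (unless `ae_params` is given), initializes the
#' cluster centers by k-means on the pretrained embedding, then alternates
#' full forward passes with Adam descent on
#' \eqn{\alpha KL(P\Vert Q) + \beta KL(P\Vert Z) + L_{res}}, refreshing the
#' target distribution P every `p_interval` epochs. Final labels are the
#' row-wise argmax of Q.
#'
#' @param X Genes x cells expression matrix (log-normalized, variable genes
#'   selected); it is transposed internally so cells are samples.
#' @param graph A `cell_graph` over the same cells.
#' @param n_clusters Number of clusters (>= 2).
#' @param weights A [loss_weights()] object.
#' @param seed Integer seed governing all randomness.
#' @param dims Encoder widths.
#' @param pretrain_epochs,epochs Pretraining / joint epochs.
#' @param lr_pretrain,lr Adam learning rates (defaults 1e-3 and 1e-4).
#' @param p_interval Target-distribution refresh interval in epochs.
#' @param v Student's-t degrees of freedom (default 1).
#' @param ae_params Optional pretrained parameters to skip pretraining.
#' @param verbose Print loss every 20 epochs.
#' @return A list of class `cluster_fit` with `labels` (1-based integers),
#'   `embedding` (cells x d), `Q`, `centers`, `history`, and `params`.
#' @export
fit_cluster_model <- function(X, graph, n_clusters, weights = loss_weights(),
                              seed = 1L, dims = c(512L, 256L, 64L),
                              pretrain_epochs = 200L, epochs = 300L,
                              lr_pretrain = 1e-3, lr = 1e-4,
                              p_interval = 5L, v = 1,
                              ae_params = NULL, verbose = FALSE) {
  validate_expression(X)
  stopifnot(inherits(graph, "cell_graph"))
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  Xc <- t(X)  # cells x features
  n <- nrow(Xc)
  if (nrow(graph$adjacency) != n) {
    stop("graph and expression matrix disagree on the number of cells",
         call. = FALSE)
  }
  A <- normalize_adjacency(graph)
  eps_f <- weights$epsilon

  if (is.null(ae_params)) {
    ae_params <- pretrain_ae(Xc, dims = dims, epochs = pretrain_epochs,
                             lr = lr_pretrain, seed = seed, verbose = verbose)
  }
  L <- length(ae_params$encoder)
  emb0 <- ae_forward_full(Xc, ae_params)$H[[L + 1L]]
  km <- kmeans_init_centers(emb0, n_clusters, seed)

  gcn_dims <- c(ncol(Xc), ae_params$dims)
  params <- with_seed(derive_seed(seed, "gcn-init"), {
    gcn <- lapply(seq_len(L), function(l) glorot(gcn_dims[l], gcn_dims[l + 1L]))
    gcn[[L + 1L]] <- glorot(gcn_dims[L + 1L], n_clusters)
    list(encoder = ae_params$encoder, decoder = ae_params$decoder,
         gcn = gcn, mu = km$centers)
  })
  m <- zeros_like(params); vstate <- zeros_like(params)
  P <- NULL
  history <- data.frame(epoch = integer(), l_res = numeric(),
                        l_clu = numeric(), l_gcn = numeric(),
                        total = numeric())
  ae_view <- function(p) list(encoder = p$encoder, decoder = p$decoder,
                              dims = ae_params$dims,
                              input_dim = ae_params$input_dim)
  Q <- NULL; fwd <- NULL; Zfused <- NULL

  for (ep in seq_len(epochs)) {
    fwd <- ae_forward_full(Xc, ae_view(params))
    H <- fwd$H
    # GCN branch, fused layer by layer with the encoder representations
    Zpre <- vector("list", L)   # pre-activations A %*% F %*% W
    Min <- vector("list", L + 1L)  # propagated inputs A %*% F
    Fused <- vector("list", L)
    Fin <- Xc
    for (l in seq_len(L)) {
      Min[[l]] <- as.matrix(A %*% Fin)
      Zpre[[l]] <- Min[[l]] %*% params$gcn[[l]]
      Zl <- relu(Zpre[[l]])
      Fused[[l]] <- combine_representations(Zl, H[[l + 1L]], eps_f)
      Fin <- Fused[[l]]
    }
    Min[[L + 1L]] <- as.matrix(A %*% Fin)
    S <- Min[[L + 1L]] %*% params$gcn[[L + 1L]]
    Zdist <- softmax_rows(S)

    emb <- H[[L + 1L]]
    Q <- soft_assign(emb, params$mu, v = v)
    if (ep == 1L || (ep - 1L) %% p_interval == 0L) {
      P <- target_distribution(Q)
    }
    l_res <- reconstruction_loss(Xc, fwd$Xhat)
    l_clu <- kl_loss(P, Q)
    l_gcn <- kl_loss(P, Zdist)
    tot <- total_loss(l_clu, l_gcn, l_res, weights)
    if (!is.finite(tot)) {
      stop(sprintf("cluster model diverged at epoch %d", ep), call. = FALSE)
    }
    history <- rbind(history, data.frame(epoch = ep, l_res = l_res,
                                         l_clu = l_clu, l_gcn = l_gcn,
                                         total = tot))

    # ---- gradients -------------------------------------------------------
    grads <- list(
      encoder = lapply(params$encoder, function(p) list(W = p$W * 0, b = p$b * 0)),
      decoder = lapply(params$decoder, function(p) list(W = p$W * 0, b = p$b * 0)),
      gcn = lapply(params$gcn, function(w) w * 0),
      mu = params$mu * 0
    )
    # GCN KL: d/dS of KL(P || softmax(S)) = Z - P
    dS <- weights$beta * (Zdist - P)
    grads$gcn[[L + 1L]] <- t(Min[[L + 1L]]) %*% dS
    dF <- as.matrix(A %*% (dS %*% t(params$gcn[[L + 1L]])))
    # external gradients flowing into each encoder representation H[[l+1]]
    dH_extra <- vector("list", L + 1L)
    for (l in L:1) {
      dZ <- (1 - eps_f) * dF
      dH_extra[[l + 1L]] <- eps_f * dF
      dpre <- dZ * (Zpre[[l]] > 0)
      grads$gcn[[l]] <- t(Min[[l]]) %*% dpre
      dF <- as.matrix(A %*% (dpre %*% t(params$gcn[[l]])))
      # dF now flows into Fused[[l-1]] (or the input, which has no gradient)
    }
    # assignment KL: DEC gradient through the Student's-t kernel
    d2 <- outer(rowSums(emb^2), rowSums(params$mu^2), "+") -
      2 * emb %*% t(params$mu)
    d2[d2 < 0] <- 0
    Wt <- (P - Q) / (1 + d2 / v)
    coef <- weights$alpha * (v + 1) / v
    dEmb_clu <- coef * (emb * rowSums(Wt) - Wt %*% params$mu)
    grads$mu <- -coef * (t(Wt) %*% emb - colSums(Wt) * params$mu)
    dH_extra[[L + 1L]] <- dH_extra[[L + 1L]] + dEmb_clu

    ae_g <- ae_backward(Xc, ae_view(params), fwd, dH_extra = dH_extra)
    grads$encoder <- ae_g$encoder
    grads$decoder <- ae_g$decoder

    st <- adam_step(params, grads, m, vstate, lr, ep)
    params <- st$p; m <- st$m; vstate <- st$v
    if (verbose && ep %% 20L == 0L) {
      message(sprintf("epoch %d: total = %.6f (res %.5f, clu %.5f, gcn %.5f)",
                      ep, tot, l_res, l_clu, l_gcn))
    }
  }
  labels <- max.col(Q, ties.method = "first")
  structure(
    list(labels = labels, embedding = ae_forward_full(Xc, ae_view(params))$H[[L + 1L]],
         Q = Q, centers = params$mu, history = history, params = params,
         n_clusters = n_clusters),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("Cluster fit: %d cells, %d clusters (sizes: %s)\n",
              length(x$labels), x$n_clusters,
              paste(tabulate(x$labels, x$n_clusters), collapse = ", ")))
  invisible(x)
}
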