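# Supervised interaction classifier.
#
# One training sample per ordered cluster pair: a (pairs x 2d) feature
# matrix whose rows hold the SVD-reduced per-cell complex-ligand expression
# over the source cluster next to the complex-receptor expression over the
# target cluster. A residual MLP (shared across pair rows) embeds the
# features; a GCN over the ligand-receptor pair correlation graph embeds
# the pairs; their row-wise dot product feeds a fully connected layer with
# sigmoid outputs, trained with focal loss against the majority-vote
# significance labels.

per_cell_complex <- function(X, subunits, cells) {
  block <- X[subunits, cells, drop = FALSE]
  if (length(subunits) == 1L) return(block[1L, ])
  out <- exp(colMeans(log(pmax(block, .Machine$double.xmin))))
  out[apply(block == 0, 2L, any)] <- 0
  out
}

# Truncated SVD of a (pairs x cells) block to (pairs x d), deterministic
# sign convention: the largest-magnitude loading of each component is made
# positive. Blocks with fewer cells than d are zero-padded.
svd_reduce <- function(B, d) {
  r <- min(dim(B), d)
  s <- svd(B, nu = r, nv = r)
  flip <- vapply(seq_len(r), function(c) {
    v <- s$v[, c]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  red <- sweep(s$u[, seq_len(r), drop = FALSE] %*%
                 diag(s$d[seq_len(r)], r, r), 2L, flip, "*")
  if (r < d) red <- cbind(red, matrix(0, nrow(B), d - r))
  red
}

#' Build per-cluster-pair feature samples for the interaction classifier
#'
#' For each ordered (source, target) cluster pair: per-cell complex-ligand
#' expression over the source cells and complex-receptor expression over
#' the target cells (geometric means across subunits per cell), each
#' (pairs x cells) block reduced to (pairs x d) by truncated SVD and
#' concatenated. Labels come from the majority-vote significance tensor.
#'
#' @param X Genes x cells expression matrix (normalized).
#' @param labels Integer cluster labels (1-based).
#' @param lridb `lridb_table` whose pairs the tensor was scored over.
#' @param tensor `cci_tensor` from [label_significant()] (supplies labels).
#' @param nodes Pair indices to use as rows (default: all pairs; normally
#'   the node list of the [build_lr_pair_graph()] output).
#' @param d SVD dimension per block (default 64).
#' @return A list of class `cci_features`: `samples` (one per ordered
#'   cluster pair with `source`, `target`, `features`, `y`), `nodes`,
#'   `pair_names`, `d`.
#' @export
build_cci_features <- function(X, labels, lridb, tensor,
                               nodes = NULL, d = 64L) {
  validate_expression(X)
  stopifnot(inherits(lridb, "lridb_table"), inherits(tensor, "cci_tensor"))
  if (is.null(nodes)) nodes <- seq_along(lridb$pairs)
  clusters <- tensor$clusters
  sizes <- table(factor(labels, levels = clusters))
  small <- clusters[sizes < 2L]
  if (length(small) > 0L) {
    stop(sprintf("cluster(s) with fewer than 2 cells: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  cells_by_cluster <- lapply(clusters, function(cl) which(labels == cl))
  lig_blocks <- vector("list", length(clusters))
  rec_blocks <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cells <- cells_by_cluster[[ci]]
    lig <- t(vapply(nodes, function(k) {
      per_cell_complex(X, lridb$pairs[[k]]$ligand, cells)
    }, numeric(length(cells))))
    rec <- t(vapply(nodes, function(k) {
      per_cell_complex(X, lridb$pairs[[k]]$receptor, cells)
    }, numeric(length(cells))))
    lig_blocks[[ci]] <- svd_reduce(lig, d)
    rec_blocks[[ci]] <- svd_reduce(rec, d)
  }
  K <- length(clusters)
  samples <- vector("list", K * K)
  s <- 0L
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      s <- s + 1L
      samples[[s]] <- list(
        source = clusters[i], target = clusters[j],
        features = cbind(lig_blocks[[i]], rec_blocks[[j]]),
        y = as.integer(tensor$significant[i, j, nodes])
      )
    }
  }
  structure(
    list(samples = samples, nodes = nodes,
         pair_names = tensor$pair_names[nodes], d = as.integer(d),
         clusters = clusters),
    class = "cci_features"
  )
}

#' Focal loss for imbalanced binary labels
#'
#' \eqn{-(1-y')^{\gamma}\log y'} for positives and
#' \eqn{-(y')^{\gamma}\log(1-y')} for negatives, averaged over elements;
#' \eqn{\gamma = 0} recovers binary cross-entropy exactly. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y Binary labels (0/1).
#' @param y_prob Predicted probabilities.
#' @param gamma Focusing exponent (default 2).
#' @return Mean loss (scalar).
#' @export
focal_loss <- function(y, y_prob, gamma = 2) {
  if (length(y) != length(y_prob)) {
    stop("y and y_prob must have equal length", call. = FALSE)
  }
  if (gamma < 0 || !is.finite(gamma)) {
    stop("gamma must be finite and >= 0", call. = FALSE)
  }
  p <- pmin(pmax(y_prob, 1e-7), 1 - 1e-7)
  loss <- ifelse(y == 1, -(1 - p)^gamma * log(p), -p^gamma * log(1 - p))
  mean(loss)
}

# d(mean focal loss)/d(p) elementwise.
focal_loss_grad <- function(y, y_prob, gamma) {
  p <- pmin(pmax(y_prob, 1e-7), 1 - 1e-7)
  g <- ifelse(
    y == 1,
    gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) - (1 - p)^gamma / p,
    -gamma * p^(pmax(gamma - 1, 0)) * log(1 - p) + p^gamma / (1 - p)
  )
  g / length(y)
}

#' Initialize interaction-model parameters
#'
#' @param n_pairs Number of graph nodes / output labels.
#' @param in_dim Feature dimension per pair row (2d).
#' @param graph `lr_pair_graph` whose profiles initialize the GCN node
#'   embeddings.
#' @param width Residual-block width (default 128).
#' @param emb_dim Branch embedding dimension for the dot product
#'   (default 32).
#' @param n_blocks Number of residual blocks (default 3).
#' @param seed Integer seed.
#' @return Parameter list of class `interaction_model_params`.
#' @export
interaction_model_init <- function(n_pairs, in_dim, graph, width = 128L,
                                   emb_dim = 32L, n_blocks = 3L, seed = 1L) {
  stopifnot(inherits(graph, "lr_pair_graph"))
  if (length(graph$nodes) != n_pairs) {
    stop("graph node count must equal n_pairs", call. = FALSE)
  }
  with_seed(seed, {
    prof <- graph$profiles
    prof <- scale(prof, center = TRUE, scale = FALSE)
    E <- prof / max(1e-8, stats::sd(prof))
    e_dim <- ncol(E)
    params <- list(
      W_in = glorot(in_dim, width), b_in = rep(0, width),
      blocks = lapply(seq_len(n_blocks), function(i) {
        list(W1 = glorot(width, width), b1 = rep(0, width),
             W2 = glorot(width, width), b2 = rep(0, width))
      }),
      W_out = glorot(width, emb_dim), b_out = rep(0, emb_dim),
      E = E,
      Wg1 = glorot(e_dim, emb_dim),
      Wg2 = glorot(emb_dim, emb_dim),
      # identity start: each pair's probability begins as a function of its
      # own dot-product logit, and cross-pair mixing is learned only if the
      # data demand it -- random dense starts entangle the pairs and do not
      # generalize across cluster-pair samples
      Wfc = diag(n_pairs) + glorot(n_pairs, n_pairs) * 0.01,
      b_fc = rep(0, n_pairs)
    )
    structure(params, class = "interaction_model_params",
              n_pairs = n_pairs, in_dim = in_dim,
              A_norm = as.matrix(normalize_adjacency(graph$adjacency)))
  })
}

# Forward pass for one sample; returns caches when cache = TRUE.
interaction_forward <- function(features, params, cache = FALSE) {
  A <- attr(params, "A_norm")
  # ResNet branch (row-shared MLP)
  pre_in <- sweep(features %*% params$W_in, 2L, params$b_in, "+")
  R <- relu(pre_in)
  block_cache <- vector("list", length(params$blocks))
  for (t in seq_along(params$blocks)) {
    bl <- params$blocks[[t]]
    pre1 <- sweep(R %*% bl$W1, 2L, bl$b1, "+")
    a1 <- relu(pre1)
    h <- sweep(a1 %*% bl$W2, 2L, bl$b2, "+")
    pre_out <- R + h
    block_cache[[t]] <- list(x = R, pre1 = pre1, a1 = a1, pre_out = pre_out)
    R <- relu(pre_out)
  }
  Rout <- sweep(R %*% params$W_out, 2L, params$b_out, "+")
  # GCN branch over the pair graph (sample-independent)
  g_pre1 <- A %*% params$E %*% params$Wg1
  G1 <- relu(g_pre1)
  G2 <- A %*% G1 %*% params$Wg2
  logits <- rowSums(Rout * G2)
  z <- as.vector(logits %*% params$Wfc) + params$b_fc
  # clamped at the focal-loss floor so outputs stay strictly inside (0, 1)
  prob <- pmin(pmax(1 / (1 + exp(-z)), 1e-7), 1 - 1e-7)
  if (!cache) return(prob)
  list(prob = prob, z = z, logits = logits, Rout = Rout, G1 = G1, G2 = G2,
       g_pre1 = g_pre1, R_final = R, pre_in = pre_in,
       block_cache = block_cache, features = features)
}

#' Interaction-model forward pass
#'
#' @param features One sample's (pairs x 2d) feature matrix.
#' @param lr_graph The `lr_pair_graph` the model was initialized with
#'   (checked for node-count agreement).
#' @param params `interaction_model_params`.
#' @return Per-pair probabilities in `(0, 1)`.
#' @export
predict_sample <- function(features, lr_graph, params) {
  if (nrow(features) != attr(params, "n_pairs")) {
    stop("feature row count does not match the model's pair count",
         call. = FALSE)
  }
  if (!is.null(lr_graph) && length(lr_graph$nodes) != attr(params, "n_pairs")) {
    stop("graph node count does not match the model", call. = FALSE)
  }
  interaction_forward(features, params)
}

interaction_backward <- function(y, fwd, params, gamma) {
  A <- attr(params, "A_norm")
  g <- list(
    W_in = params$W_in * 0, b_in = params$b_in * 0,
    blocks = lapply(params$blocks, function(bl) {
      list(W1 = bl$W1 * 0, b1 = bl$b1 * 0, W2 = bl$W2 * 0, b2 = bl$b2 * 0)
    }),
    W_out = params$W_out * 0, b_out = params$b_out * 0,
    E = params$E * 0, Wg1 = params$Wg1 * 0, Wg2 = params$Wg2 * 0,
    Wfc = params$Wfc * 0, b_fc = params$b_fc * 0
  )
  dprob <- focal_loss_grad(y, fwd$prob, gamma)
  dz <- dprob * fwd$prob * (1 - fwd$prob)
  g$Wfc <- outer(fwd$logits, dz)
  g$b_fc <- dz
  dlogits <- as.vector(params$Wfc %*% dz)
  dRout <- dlogits * fwd$G2
  dG2 <- dlogits * fwd$Rout
  # GCN branch (A is symmetric, so A^T propagation reuses A)
  g$Wg2 <- t(as.matrix(A %*% fwd$G1)) %*% dG2
  dG1 <- as.matrix(A %*% dG2 %*% t(params$Wg2))
  dgpre1 <- dG1 * (as.matrix(fwd$g_pre1) > 0)
  g$Wg1 <- t(as.matrix(A %*% params$E)) %*% dgpre1
  g$E <- as.matrix(A %*% dgpre1 %*% t(params$Wg1))
  # ResNet branch
  g$W_out <- t(fwd$R_final) %*% dRout
  g$b_out <- colSums(dRout)
  dR <- dRout %*% t(params$W_out)
  for (t in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[t]]
    cc <- fwd$block_cache[[t]]
    dpre_out <- dR * (cc$pre_out > 0)
    dh <- dpre_out
    g$blocks[[t]]$W2 <- t(cc$a1) %*% dh
    g$blocks[[t]]$b2 <- colSums(dh)
    da1 <- dh %*% t(bl$W2)
    dpre1 <- da1 * (cc$pre1 > 0)
    g$blocks[[t]]$W1 <- t(cc$x) %*% dpre1
    g$blocks[[t]]$b1 <- colSums(dpre1)
    dR <- dpre_out + dpre1 %*% t(bl$W1)
  }
  dpre_in <- dR * (fwd$pre_in > 0)
  g$W_in <- t(fwd$features) %*% dpre_in
  g$b_in <- colSums(dpre_in)
  g
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

train_interaction_net <- function(samples, params, gamma, epochs, lr,
                                  verbose = FALSE) {
  core <- unclass(params)
  attrs <- attributes(params)
  m <- zeros_like(core); v <- zeros_like(core)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    total <- 0
    grads <- NULL
    for (s in samples) {
      fwd <- interaction_forward(s$features, params, cache = TRUE)
      total <- total + focal_loss(s$y, fwd$prob, gamma)
      gs <- interaction_backward(s$y, fwd, params, gamma)
      grads <- if (is.null(grads)) gs else add_grads(grads, gs)
    }
    history[ep] <- total / length(samples)
    st <- adam_step(core, grads, m, v, lr, ep)
    core <- st$p; m <- st$m; v <- st$v
    attributes(core) <- attrs
    params <- core
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("interaction epoch %d: loss %.5f", ep, history[ep]))
    }
  }
  attr(params, "loss_history") <- history
  params
}

# Round-robin stratified fold assignment by positive-label density.
stratified_folds <- function(samples, folds, seed) {
  density <- vapply(samples, function(s) mean(s$y), 0)
  ord <- with_seed(seed, order(density, stats::runif(length(density))))
  fold <- integer(length(samples))
  fold[ord] <- rep_len(seq_len(folds), length(samples))
  fold
}

#' Train the interaction classifier with cross-validation
#'
#' Samples (ordered cluster pairs) are split into folds stratified by
#' positive-label density; each fold is held out in turn while the model is
#' trained on the rest with focal loss and full-batch Adam. Per-fold
#' held-out recall, precision, accuracy, F1 (at the 0.5 threshold) and AUC
#' are reported; AUC is `NA` with a warning for folds without both classes.
#'
#' @param featureset `cci_features` from [build_cci_features()].
#' @param lr_graph `lr_pair_graph` over the same node pairs.
#' @param gamma Focal-loss exponent (default 2).
#' @param folds Number of CV folds (default 5).
#' @param repeats Training repetitions per fold (default 1; metrics are
#'   averaged).
#' @param seed Integer seed.
#' @param epochs,lr Training epochs and Adam learning rate.
#' @param width,emb_dim Network sizes (see [interaction_model_init()]).
#' @return A list of class `interaction_cv` with `models` (one per fold),
#'   `metrics` (data.frame: fold, recall, precision, acc, f1, auc),
#'   `fold_assignment`, and `predictions` (held-out probabilities, long
#'   format).
#' @export
train_interaction_model <- function(featureset, lr_graph, gamma = 2,
                                    folds = 5L, repeats = 1L, seed = 1L,
                                    epochs = 120L, lr = 1e-3,
                                    width = 128L, emb_dim = 32L) {
  stopifnot(inherits(featureset, "cci_features"),
            inherits(lr_graph, "lr_pair_graph"))
  samples <- featureset$samples
  if (length(samples) < folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  n_pairs <- length(lr_graph$nodes)
  in_dim <- ncol(samples[[1L]]$features)
  fold_of <- stratified_folds(samples, folds, derive_seed(seed, "folds"))
  models <- vector("list", folds)
  metrics <- vector("list", folds)
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    train_idx <- which(fold_of != f)
    test_idx <- which(fold_of == f)
    fold_metrics <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      params <- interaction_model_init(
        n_pairs, in_dim, lr_graph, width = width, emb_dim = emb_dim,
        seed = derive_seed(seed, sprintf("fold%d-rep%d", f, r))
      )
      params <- train_interaction_net(samples[train_idx], params, gamma,
                                      epochs, lr)
      pred <- lapply(samples[test_idx], function(s) {
        list(prob = interaction_forward(s$features, params), y = s$y,
             source = s$source, target = s$target)
      })
      probs <- unlist(lapply(pred, `[[`, "prob"))
      ys <- unlist(lapply(pred, `[[`, "y"))
      call <- as.integer(probs >= 0.5)
      cm <- confusion_metrics(
        TP = sum(call == 1 & ys == 1), TN = sum(call == 0 & ys == 0),
        FP = sum(call == 1 & ys == 0), FN = sum(call == 0 & ys == 1)
      )
      auc <- if (length(unique(ys)) < 2L) {
        warning(sprintf("fold %d has a single class; AUC undefined", f),
                call. = FALSE)
        NA_real_
      } else {
        roc_auc(probs, ys)
      }
      fold_metrics[[r]] <- data.frame(
        fold = f, repeat_ = r, recall = cm$recall, precision = cm$precision,
        acc = cm$acc, f1 = cm$f1, auc = auc
      )
      if (r == repeats) {
        models[[f]] <- params
        preds[[f]] <- do.call(rbind, lapply(pred, function(p) {
          data.frame(source_cluster = p$source, target_cluster = p$target,
                     pair = featureset$pair_names, probability = p$prob,
                     label = p$y, fold = f, stringsAsFactors = FALSE)
        }))
      }
    }
    metrics[[f]] <- do.call(rbind, fold_metrics)
  }
  structure(
    list(models = models, metrics = do.call(rbind, metrics),
         fold_assignment = fold_of, predictions = do.call(rbind, preds),
         featureset = featureset),
    class = "interaction_cv"
  )
}

#' @export
print.interaction_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Interaction model CV: %d fold(s); mean AUC %.3f, mean F1 %.3f\n",
    max(m$fold), mean(m$auc, na.rm = TRUE), mean(m$f1, na.rm = TRUE)
  ))
  invisible(x)
}

#' Predict interactions with a trained model
#'
#' @param model Trained `interaction_model_params` (e.g. one element of an
#'   `interaction_cv`'s `models`).
#' @param featureset `cci_features` with the same pair layout as training.
#' @param threshold Call threshold (default 0.5); a probability exactly at
#'   the threshold is called positive.
#' @return Long-format data frame: source_cluster, target_cluster, ligand,
#'   receptor, probability, call.
#' @export
predict_interactions <- function(model, featureset, threshold = 0.5) {
  stopifnot(inherits(featureset, "cci_features"))
  if (ncol(featureset$samples[[1L]]$features) != attr(model, "in_dim") ||
      nrow(featureset$samples[[1L]]$features) != attr(model, "n_pairs")) {
    stop("feature layout does not match the trained model", call. = FALSE)
  }
  lig <- sub("->.*$", "", featureset$pair_names)
  rec <- sub("^.*->", "", featureset$pair_names)
  out <- lapply(featureset$samples, function(s) {
    prob <- interaction_forward(s$features, model)
    data.frame(source_cluster = s$source, target_cluster = s$target,
               ligand = lig, receptor = rec, probability = prob,
               call = as.integer(prob >= threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
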