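# Interaction probability and significance labelling.
#
# The probability of an interaction from source cluster i to target cluster
# j through pair k is the product of the cluster-level ligand and receptor
# complex summaries, each a geometric mean over subunit truncated means.
# Significance is a majority vote over three scorers: a regularized-product
# score (SingleCellSignalR-style), a permutation test on plain mean
# products (CellPhoneDB-style), and a permutation test on truncated-mean
# products (CellChat-style).

#' Complex expression summary
#'
#' Geometric mean of the subunit summaries; zero expression of any subunit
#' renders the whole complex inactive (zero).
#'
#' @param subunit_summaries Non-negative numeric vector, one entry per
#'   subunit.
#' @return Non-negative scalar.
#' @export
complex_expression <- function(subunit_summaries) {
  if (length(subunit_summaries) == 0L) {
    stop("subunit_summaries must be non-empty", call. = FALSE)
  }
  geometric_mean(subunit_summaries)
}

#' Interaction probability of a ligand-receptor pair
#'
#' Product of the source cluster's complex-ligand summary and the target
#' cluster's complex-receptor summary.
#'
#' @param L_i,R_j Non-negative complex summaries.
#' @return Non-negative scalar.
#' @export
interaction_probability <- function(L_i, R_j) {
  if (L_i < 0 || R_j < 0) stop("summaries must be >= 0", call. = FALSE)
  L_i * R_j
}

#' Regularized-product ligand-receptor score
#'
#' \eqn{\sqrt{lr} / (\mu + \sqrt{lr})}, in `[0, 1)`; `mu` is conventionally
#' the mean of the processed expression matrix, so the score is 0.5 exactly
#' when the product's square root matches the dataset-wide mean.
#'
#' @param l,r Non-negative cluster-level ligand and receptor summaries.
#' @param mu Positive regularization constant.
#' @return Score in `[0, 1)`.
#' @export
lrscore <- function(l, r, mu) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (l < 0 || r < 0) stop("l and r must be >= 0", call. = FALSE)
  s <- sqrt(l * r)
  s / (mu + s)
}

#' Majority vote over three significance calls
#'
#' @param votes Logical vector of exactly three votes.
#' @return `TRUE` iff at least two votes are `TRUE`.
#' @export
majority_vote <- function(votes) {
  if (length(votes) != 3L || !is.logical(votes)) {
    stop("votes must be exactly three logicals", call. = FALSE)
  }
  sum(votes) >= 2L
}

# Cluster-level plain and truncated mean summaries for a gene subset.
cluster_summaries <- function(X, labels, clusters, trunc = 0.10) {
  mean_mat <- matrix(0, nrow(X), length(clusters),
                     dimnames = list(rownames(X), NULL))
  tmean_mat <- mean_mat
  for (ci in seq_along(clusters)) {
    sub <- X[, labels == clusters[ci], drop = FALSE]
    mean_mat[, ci] <- rowMeans(sub)
    tmean_mat[, ci] <- truncated_row_means(sub, trunc)
  }
  list(mean = mean_mat, tmean = tmean_mat)
}

# Complex summary per cluster for one side of one pair, from a genes x
# clusters summary matrix.
complex_by_cluster <- function(summ, subunits) {
  if (length(subunits) == 1L) return(summ[subunits, ])
  apply(summ[subunits, , drop = FALSE], 2L, geometric_mean)
}

#' Permutation p-value for one cluster-pair ligand-receptor statistic
#'
#' The statistic is the product of the source cluster's complex-ligand
#' summary and the target cluster's complex-receptor summary, with
#' summaries either plain means or 10 percent truncated means. Cluster
#' labels are permuted over cells; the add-one estimator
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(1 + B)} keeps p-values
#' in \eqn{[1/(B+1), 1]}.
#'
#' @param X Genes x cells expression matrix.
#' @param labels Integer cluster labels (1-based).
#' @param pair List with `ligand`, `receptor` (subunit symbol vectors),
#'   `source`, `target` (cluster ids); an `lr_pair` plus `source`/`target`
#'   entries also works.
#' @param statistic `"mean-product"` or `"truncated-mean-product"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param trunc Truncation fraction for the truncated variant.
#' @return P-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(X, labels, pair,
                               statistic = c("mean-product",
                                             "truncated-mean-product"),
                               n_perm = 1000L, seed = 1L, trunc = 0.10) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("need at least two clusters to permute against", call. = FALSE)
  }
  genes <- c(pair$ligand, pair$receptor)
  if (!all(genes %in% rownames(X))) {
    stop("pair subunits missing from the expression matrix", call. = FALSE)
  }
  summarise <- function(lab) {
    src <- X[, lab == pair$source, drop = FALSE]
    tgt <- X[, lab == pair$target, drop = FALSE]
    f <- if (statistic == "mean-product") rowMeans else {
      function(m) truncated_row_means(m, trunc)
    }
    l <- geometric_mean(f(src[pair$ligand, , drop = FALSE]))
    r <- geometric_mean(f(tgt[pair$receptor, , drop = FALSE]))
    l * r
  }
  obs <- summarise(labels)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (summarise(sample(labels)) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
}

#' Score and label all cluster-pair ligand-receptor interactions
#'
#' For every (source cluster, target cluster, pair) triple: the interaction
#' probability from 10 percent truncated cluster means with geometric-mean
#' complexes; three significance votes (regularized-product score at
#' `lrscore_threshold`, permutation test on plain mean products and on
#' truncated-mean products, each at `pval_threshold`); and the final
#' majority-vote significance flag. All permutations share one label
#' shuffle per iteration, so the full tensor costs the same as a single
#' test.
#'
#' @param X Genes x cells expression matrix (normalized).
#' @param labels Integer cluster labels (1-based).
#' @param lridb An `lridb_table` already filtered to the dataset's genes.
#' @param lrscore_threshold Vote 1 threshold (default 0.5).
#' @param pval_threshold Votes 2-3 threshold (default 0.01).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @param trunc Truncation fraction (default 0.10).
#' @return A list of class `cci_tensor`: arrays `probability`, `lrscore`,
#'   `pval_mean`, `pval_trunc`, `votes`, `significant`, all indexed
#'   (source, target, pair), plus `clusters` and `pair_names`.
#' @export
label_significant <- function(X, labels, lridb, lrscore_threshold = 0.5,
                              pval_threshold = 0.01, n_perm = 1000L,
                              seed = 1L, trunc = 0.10) {
  validate_expression(X)
  stopifnot(inherits(lridb, "lridb_table"))
  if (length(lridb$pairs) == 0L) {
    stop("no ligand-receptor pairs to score", call. = FALSE)
  }
  genes <- unique(unlist(lapply(lridb$pairs, function(p) c(p$ligand, p$receptor))))
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0L) {
    stop(sprintf("lridb must be filtered to the dataset's genes (missing: %s)",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  clusters <- sort(unique(labels))
  K <- length(clusters)
  n_pairs <- length(lridb$pairs)
  Xg <- X[genes, , drop = FALSE]
  obs <- cluster_summaries(Xg, labels, clusters, trunc)
  mu_global <- mean(X)

  lig_t <- matrix(0, n_pairs, K)  # truncated complex summaries per cluster
  rec_t <- matrix(0, n_pairs, K)
  lig_m <- matrix(0, n_pairs, K)  # plain-mean complex summaries
  rec_m <- matrix(0, n_pairs, K)
  for (k in seq_len(n_pairs)) {
    p <- lridb$pairs[[k]]
    lig_t[k, ] <- complex_by_cluster(obs$tmean, p$ligand)
    rec_t[k, ] <- complex_by_cluster(obs$tmean, p$receptor)
    lig_m[k, ] <- complex_by_cluster(obs$mean, p$ligand)
    rec_m[k, ] <- complex_by_cluster(obs$mean, p$receptor)
  }
  pair_names <- vapply(lridb$pairs, function(p) {
    sprintf("%s->%s", paste(p$ligand, collapse = "+"),
            paste(p$receptor, collapse = "+"))
  }, "")
  dn <- list(paste0("cluster", clusters), paste0("cluster", clusters),
             pair_names)
  prob <- array(0, c(K, K, n_pairs), dimnames = dn)
  score <- prob
  stat_mean <- prob
  stat_trunc <- prob
  for (k in seq_len(n_pairs)) {
    prob[, , k] <- outer(lig_t[k, ], rec_t[k, ])
    stat_mean[, , k] <- outer(lig_m[k, ], rec_m[k, ])
    stat_trunc[, , k] <- prob[, , k]
    score[, , k] <- {
      s <- sqrt(outer(lig_m[k, ], rec_m[k, ]))
      s / (mu_global + s)
    }
  }

  hits_mean <- array(0L, c(K, K, n_pairs))
  hits_trunc <- array(0L, c(K, K, n_pairs))
  with_seed(derive_seed(seed, "perm"), {
    for (b in seq_len(n_perm)) {
      perm <- cluster_summaries(Xg, sample(labels), clusters, trunc)
      for (k in seq_len(n_pairs)) {
        p <- lridb$pairs[[k]]
        lm <- complex_by_cluster(perm$mean, p$ligand)
        rm_ <- complex_by_cluster(perm$mean, p$receptor)
        lt <- complex_by_cluster(perm$tmean, p$ligand)
        rt <- complex_by_cluster(perm$tmean, p$receptor)
        hits_mean[, , k] <- hits_mean[, , k] +
          (outer(lm, rm_) >= stat_mean[, , k])
        hits_trunc[, , k] <- hits_trunc[, , k] +
          (outer(lt, rt) >= stat_trunc[, , k])
      }
    }
  })
  pval_mean <- (1 + hits_mean) / (1 + n_perm)
  pval_trunc <- (1 + hits_trunc) / (1 + n_perm)
  dimnames(pval_mean) <- dn
  dimnames(pval_trunc) <- dn
  votes <- (score >= lrscore_threshold) + (pval_mean <= pval_threshold) +
    (pval_trunc <= pval_threshold)
  significant <- votes >= 2L
  structure(
    list(probability = prob, lrscore = score, pval_mean = pval_mean,
         pval_trunc = pval_trunc, votes = votes, significant = significant,
         clusters = clusters, pair_names = pair_names,
         thresholds = list(lrscore = lrscore_threshold, pval = pval_threshold),
         n_perm = n_perm),
    class = "cci_tensor"
  )
}

#' @export
print.cci_tensor <- function(x, ...) {
  cat(sprintf(
    "Interaction tensor: %d x %d clusters, %d pair(s); %d significant triple(s)\n",
    length(x$clusters), length(x$clusters), length(x$pair_names),
    sum(x$significant)
  ))
  invisible(x)
}

#' Flatten an interaction tensor to long format
#'
#' @param x A `cci_tensor`.
#' @param ... Unused.
#' @return Data frame with one row per (source, target, pair): columns
#'   source_cluster, target_cluster, ligand, receptor, probability, lrscore,
#'   pval_mean, pval_trunc, votes, significant.
#' @export
as.data.frame.cci_tensor <- function(x, ...) {
  K <- length(x$clusters)
  n_pairs <- length(x$pair_names)
  idx <- expand.grid(source = seq_len(K), target = seq_len(K),
                     pair = seq_len(n_pairs))
  lig <- sub("->.*$", "", x$pair_names)
  rec <- sub("^.*->", "", x$pair_names)
  flat <- function(a) a[cbind(idx$source, idx$target, idx$pair)]
  data.frame(
    source_cluster = x$clusters[idx$source],
    target_cluster = x$clusters[idx$target],
    ligand = lig[idx$pair],
    receptor = rec[idx$pair],
    probability = flat(x$probability),
    lrscore = flat(x$lrscore),
    pval_mean = flat(x$pval_mean),
    pval_trunc = flat(x$pval_trunc),
    votes = flat(x$votes),
    significant = flat(x$significant),
    stringsAsFactors = FALSE
  )
}
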