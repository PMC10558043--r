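#' Build a K-nearest-neighbour cell graph
#'
#' Each cell is connected to its `K` Euclidean nearest neighbours; the
#' directed KNN relation is symmetrized by union, giving a simple undirected
#' graph with zero diagonal. Distance ties break deterministically by
#' ascending cell index.
#'
#' @param features Cells x d numeric matrix (e.g. PCA scores of the
#'   log-normalized variable-gene matrix).
#' @param K Number of neighbours (default 10); must satisfy `K < n_cells`.
#' @return A list of class `cell_graph` with sparse binary `adjacency` and
#'   `K`.
#' @export
build_knn_graph <- function(features, K = 10L) {
  stopifnot_matrix(features, "features")
  n <- nrow(features)
  if (K < 1L || K >= n) {
    stop(sprintf("K must satisfy 1 <= K < n_cells (= %d)", n), call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(features))^2
  diag(d2) <- Inf
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(K)]
    ii <- c(ii, rep.int(i, K))
    jj <- c(jj, nb)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  A@x[] <- 1  # union symmetrization, binary
  structure(list(adjacency = A, K = as.integer(K)), class = "cell_graph")
}

#' Symmetrically normalize an adjacency matrix
#'
#' Adds self-loops and rescales:
#' \deqn{\tilde A = A + I,\quad \hat A = \tilde D^{-1/2}\tilde A\tilde D^{-1/2}}
#' with \eqn{\tilde D_{ii} = \sum_j \tilde A_{ij}}. This is the propagation
#' operator used by every graph-convolution layer; its spectral radius is at
#' most 1.
#'
#' @param A Square symmetric binary adjacency (base or Matrix).
#' @return Sparse symmetric normalized adjacency.
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "cell_graph")) A <- A$adjacency
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  At <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  D <- Matrix::Diagonal(x = dinv)
  D %*% At %*% D
}

#' Estimate the number of clusters by Louvain community detection
#'
#' Runs Louvain modularity optimisation (resolution 1.0) on the cell graph
#' under a fixed seed and returns the community count. Used to pick the
#' cluster number when the user does not supply one.
#'
#' @param graph A `cell_graph` (or square adjacency).
#' @param seed Integer seed for the (stochastic) Louvain sweep order.
#' @param resolution Modularity resolution (default 1.0).
#' @return Integer number of communities.
#' @export
estimate_n_clusters <- function(graph, seed = 1L, resolution = 1.0) {
  A <- if (inherits(graph, "cell_graph")) graph$adjacency else graph
  if (nrow(A) == 0L) stop("graph is empty", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  length(unique(igraph::membership(comm)))
}

#' Build the ligand-receptor pair correlation graph
#'
#' Nodes are the `top_n` pairs with the largest total interaction
#' probability summed over all (source, target) cluster combinations (ties
#' by pair index). Edges come from the Pearson correlation of the pairs'
#' probability profiles across the flattened cluster-pair axis. In the
#' default `"magnitude"` mode, an edge is placed where `|corr| >= tau`; the
#' `"literal"` mode instead places an edge where `corr < tau`, reproducing
#' the published thresholding rule verbatim (see the methods vignette for
#' why the default inverts it).
#'
#' @param prob A `cci_tensor` from [label_significant()], or a plain
#'   (source x target x pair) array.
#' @param top_n Number of node pairs (default 200).
#' @param tau Correlation threshold (default 0.95).
#' @param mode `"magnitude"` (default) or `"literal"`.
#' @return A list of class `lr_pair_graph` with `nodes` (pair indices into
#'   the tensor), `node_names`, `scores`, `correlation`, `adjacency`,
#'   `tau`, and `profiles` (nodes x cluster-combination probability matrix).
#' @export
build_lr_pair_graph <- function(prob, top_n = 200L, tau = 0.95,
                                mode = c("magnitude", "literal")) {
  mode <- match.arg(mode)
  arr <- if (inherits(prob, "cci_tensor")) prob$probability else prob
  if (length(dim(arr)) != 3L) {
    stop("probability tensor must be 3-dimensional", call. = FALSE)
  }
  n_pairs <- dim(arr)[3L]
  if (n_pairs < 1L) stop("tensor has no pairs", call. = FALSE)
  n_combo <- dim(arr)[1L] * dim(arr)[2L]
  if (n_combo < 2L) {
    stop("need at least two (source, target) cluster combinations",
         call. = FALSE)
  }
  profiles <- t(apply(arr, 3L, as.vector))  # pairs x combos
  scores <- rowSums(profiles)
  ord <- order(-scores, seq_len(n_pairs))
  nodes <- ord[seq_len(min(top_n, n_pairs))]
  prof <- profiles[nodes, , drop = FALSE]
  sds <- apply(prof, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf(
      "%d pair(s) have zero variance across cluster combinations; their correlations are set to 0",
      sum(sds == 0)), call. = FALSE)
  }
  cmat <- matrix(0, length(nodes), length(nodes))
  ok <- sds > 0
  if (sum(ok) >= 2L) {
    cmat[ok, ok] <- stats::cor(t(prof[ok, , drop = FALSE]))
  }
  diag(cmat) <- 1
  adj <- if (mode == "magnitude") abs(cmat) >= tau else cmat < tau
  adj <- adj * 1
  diag(adj) <- 0
  node_names <- if (inherits(prob, "cci_tensor")) {
    prob$pair_names[nodes]
  } else {
    dimnames(arr)[[3L]][nodes]
  }
  structure(
    list(nodes = nodes, node_names = node_names, scores = scores[nodes],
         correlation = cmat, adjacency = adj, tau = tau, mode = mode,
         profiles = prof),
    class = "lr_pair_graph"
  )
}

#' Export a graph as an edge-list TSV
#'
#' @param graph A `cell_graph` or `lr_pair_graph`.
#' @param path Output TSV path (columns node_u, node_v, weight).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  A <- if (inherits(graph, "cell_graph")) graph$adjacency else graph$adjacency
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "TsparseMatrix")
  keep <- A@i < A@j
  df <- data.frame(node_u = A@i[keep] + 1L, node_v = A@j[keep] + 1L,
                   weight = A@x[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
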