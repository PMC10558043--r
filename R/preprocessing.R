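#' Read a gene x cell expression matrix
#'
#' Supports Matrix Market triplet files with `genes.tsv` / `barcodes.tsv`
#' sidecars (10x-style layout) and dense CSV/TSV with genes as rows and a
#' header row of cell barcodes.
#'
#' @param path Path to a `.mtx` file or a dense CSV/TSV.
#' @param genes_path,barcodes_path Sidecar paths for the MTX layout.
#'   Default: `genes.tsv` and `barcodes.tsv` next to the matrix.
#' @return A dense genes x cells numeric matrix with dimnames.
#' @export
read_expression <- function(path, genes_path = NULL, barcodes_path = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("expression input not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.mtx$", path)) {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    for (p in c(genes_path, barcodes_path)) {
      if (!file.exists(p)) {
        stop(sprintf("sidecar file not found: %s", p), call. = FALSE)
      }
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
      stop("sidecar lengths do not match matrix dimensions", call. = FALSE)
    }
    dimnames(m) <- list(genes, barcodes)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
  }
  if (any(m < 0)) stop("expression matrix has negative entries", call. = FALSE)
  validate_expression(m)
  m
}

validate_expression <- function(X) {
  stopifnot_matrix(X, "X")
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop("expression matrix needs gene rownames and cell colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X))) stop("duplicate gene names", call. = FALSE)
  if (anyDuplicated(colnames(X))) stop("duplicate cell barcodes", call. = FALSE)
  invisible(X)
}

#' Quality-control filter on genes and cells
#'
#' Keeps genes nonzero in strictly more than `gene_frac` of cells, then cells
#' nonzero in strictly more than `cell_frac` of the retained genes (in that
#' order, a single pass).
#'
#' @param X Genes x cells matrix.
#' @param gene_frac,cell_frac Fractions in `[0, 1)`. Default 0.01, i.e. the
#'   "more than 1 percent" convention.
#' @return The filtered matrix; errors if no genes or no cells survive.
#' @export
qc_filter <- function(X, gene_frac = 0.01, cell_frac = 0.01) {
  validate_expression(X)
  if (gene_frac < 0 || gene_frac >= 1 || cell_frac < 0 || cell_frac >= 1) {
    stop("fractions must lie in [0, 1)", call. = FALSE)
  }
  keep_genes <- rowSums(X > 0) / ncol(X) > gene_frac
  if (!any(keep_genes)) stop("no genes survive QC", call. = FALSE)
  X <- X[keep_genes, , drop = FALSE]
  keep_cells <- colSums(X > 0) / nrow(X) > cell_frac
  if (!any(keep_cells)) stop("no cells survive QC", call. = FALSE)
  X[, keep_cells, drop = FALSE]
}

#' Depth-normalize and log-transform
#'
#' Scales each cell to `scale` total counts, then applies `log(1 + v)`
#' elementwise (natural log).
#'
#' @param X Genes x cells matrix.
#' @param scale Target per-cell total (default 10000).
#' @return Transformed matrix of the same shape.
#' @export
normalize_log <- function(X, scale = 10000) {
  validate_expression(X)
  totals <- colSums(X)
  zero <- which(totals == 0)
  if (length(zero) > 0L) {
    stop(sprintf("cell(s) with zero total count: %s",
                 paste(colnames(X)[zero], collapse = ", ")), call. = FALSE)
  }
  log1p(sweep(X, 2L, totals / scale, "/"))
}

#' Select highly variable genes
#'
#' Ranks genes by per-gene standard deviation and keeps the top `n_top`,
#' preserving the original gene order. If fewer genes exist, all are kept
#' with a warning.
#'
#' @param X Genes x cells matrix (typically log-normalized).
#' @param n_top Number of genes to keep (default 2000).
#' @return Row-restricted matrix.
#' @export
select_hvg <- function(X, n_top = 2000L) {
  validate_expression(X)
  if (n_top < 1L) stop("n_top must be >= 1", call. = FALSE)
  if (n_top >= nrow(X)) {
    if (n_top > nrow(X)) {
      warning(sprintf("only %d genes available; keeping all", nrow(X)),
              call. = FALSE)
    }
    return(X)
  }
  sds <- apply(X, 1L, stats::sd)
  keep <- sort(order(sds, decreasing = TRUE)[seq_len(n_top)])
  X[keep, , drop = FALSE]
}

#' One-vs-rest Wilcoxon rank-sum differential expression
#'
#' For each cluster and each requested gene, tests the cluster's cells
#' against all remaining cells. The over-expressed flag is
#' `p <= alpha` under the configured alternative (default one-sided
#' "greater", since the pipeline looks for over-expressed signalling genes).
#'
#' @param X Genes x cells matrix.
#' @param labels Integer cluster label per cell (1-based).
#' @param alpha Significance level (default 0.05, unadjusted).
#' @param genes Genes to test; default all rows.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"`.
#' @return Data frame with columns cluster, gene, statistic, p_value,
#'   overexpressed. Clusters of size < 2 get `NA` results rather than being
#'   dropped.
#' @export
wilcoxon_de <- function(X, labels, alpha = 0.05, genes = rownames(X),
                        alternative = c("greater", "two.sided"),
                        adjust = "none") {
  validate_expression(X)
  alternative <- match.arg(alternative)
  if (length(labels) != ncol(X)) {
    stop("labels length must equal the number of cells", call. = FALSE)
  }
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    stop("need at least two clusters for differential expression",
         call. = FALSE)
  }
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes) > 0L) {
    stop(sprintf("genes not in matrix: %s",
                 paste(utils::head(missing_genes, 5L), collapse = ", ")),
         call. = FALSE)
  }
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    in_cl <- labels == cl
    if (sum(in_cl) < 2L) {
      out[[ci]] <- data.frame(
        cluster = cl, gene = genes, statistic = NA_real_,
        p_value = NA_real_, overexpressed = NA, stringsAsFactors = FALSE
      )
      next
    }
    stats_p <- vapply(genes, function(g) {
      wt <- suppressWarnings(stats::wilcox.test(
        X[g, in_cl], X[g, !in_cl], alternative = alternative
      ))
      c(wt$statistic, wt$p.value)
    }, c(0, 0))
    p <- stats::p.adjust(stats_p[2L, ], method = adjust)
    out[[ci]] <- data.frame(
      cluster = cl, gene = genes, statistic = unname(stats_p[1L, ]),
      p_value = unname(p), overexpressed = unname(p <= alpha),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Restrict a ligand-receptor table to over-expressed, PPI-supported pairs
#'
#' A pair survives when every ligand subunit and every receptor subunit is
#' over-expressed in at least one cluster, and -- when a protein-protein
#' interaction edge list is supplied -- at least one (ligand subunit,
#' receptor subunit) combination is a PPI edge (undirected). An empty edge
#' set skips the PPI condition with a logged notice.
#'
#' @param de Result of [wilcoxon_de()].
#' @param ppi_edges Two-column matrix or data frame of gene symbols, or
#'   `NULL`/empty to skip.
#' @param lridb An `lridb_table`.
#' @return Filtered `lridb_table`.
#' @export
ppi_project <- function(de, ppi_edges, lridb) {
  stopifnot(inherits(lridb, "lridb_table"))
  over <- unique(de$gene[!is.na(de$overexpressed) & de$overexpressed])
  use_ppi <- !is.null(ppi_edges) && NROW(ppi_edges) > 0L
  if (use_ppi) {
    ppi_edges <- as.matrix(ppi_edges)[, 1:2, drop = FALSE]
    edge_keys <- c(paste(ppi_edges[, 1L], ppi_edges[, 2L]),
                   paste(ppi_edges[, 2L], ppi_edges[, 1L]))
  } else {
    message("empty PPI edge list; skipping the PPI support condition")
    edge_keys <- character()
  }
  keep <- vapply(lridb$pairs, function(p) {
    if (!all(p$ligand %in% over) || !all(p$receptor %in% over)) return(FALSE)
    if (!use_ppi) return(TRUE)
    any(outer(p$ligand, p$receptor, paste) %in% edge_keys)
  }, NA)
  new_lridb_table(lridb$pairs[keep], lridb$species)
}

#' Truncated mean
#'
#' Drops `floor(trunc * n)` smallest and as many largest values, then takes
#' the arithmetic mean of what remains. The per-tail 10 percent default is
#' the summary used for cluster-level ligand and receptor expression, damping
#' extreme values in sparse counts.
#'
#' @param values Non-empty numeric vector.
#' @param trunc Per-tail truncation fraction in `[0, 0.5)`.
#' @return The truncated mean.
#' @export
truncated_mean <- function(values, trunc = 0.10) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (trunc < 0 || trunc >= 0.5) {
    stop("trunc must lie in [0, 0.5)", call. = FALSE)
  }
  n <- length(values)
  drop <- floor(trunc * n)
  if (drop == 0L) return(mean(values))
  s <- sort(values)
  mean(s[(drop + 1L):(n - drop)])
}

# Row-wise truncated means of a genes x cells block: used heavily inside the
# permutation tests, where per-call overhead matters.
truncated_row_means <- function(M, trunc = 0.10) {
  n <- ncol(M)
  drop <- floor(trunc * n)
  if (drop == 0L) return(rowMeans(M))
  idx <- (drop + 1L):(n - drop)
  apply(M, 1L, function(v) mean(sort.int(v, method = "quick")[idx]))
}

#' Read a two-column cell label CSV
#'
#' @param path CSV with columns (barcode, label), no header required but one
#'   is tolerated.
#' @param barcodes Barcodes the labels must cover, in matrix column order.
#' @return Integer vector of 1-based cluster labels aligned to `barcodes`.
#' @export
read_labels <- function(path, barcodes) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1L, 1L]), "barcode")) df <- df[-1L, , drop = FALSE]
  lab <- stats::setNames(df[[2L]], df[[1L]])
  missing <- setdiff(barcodes, names(lab))
  if (length(missing) > 0L) {
    stop(sprintf("labels missing for %d barcode(s), e.g. %s",
                 length(missing), missing[1L]), call. = FALSE)
  }
  as.integer(factor(lab[barcodes]))
}
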