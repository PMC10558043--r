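#' Specify a synthetic single-cell expression dataset
#'
#' The generator plants disjoint marker-gene blocks per cluster in
#' negative-binomial counts, which is the structure the clustering and
#' interaction-scoring statistics assume: over-dispersed UMI-like counts,
#' cluster-specific over-expression, and (optionally, via
#' [plant_lr_signal()]) cognate ligand/receptor over-expression in
#' source/target clusters.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param n_clusters Number of planted clusters.
#' @param proportions Cluster proportions, summing to 1. Default equal.
#' @param baseline_mean Mean of the negative-binomial baseline (default 1,
#'   a typical shallow UMI depth per gene).
#' @param dispersion Gene-level negative-binomial dispersion (default 0.3,
#'   i.e. size = 1/0.3).
#' @param de_strength Fold-change applied to each cluster's marker block
#'   (default 8; 1 means no planted structure).
#' @param markers_per_cluster Marker genes per cluster (default 40).
#' @param lridb Optional `lridb_table` (e.g. from [make_toy_lridb()]); its
#'   subunit genes are embedded into the matrix as dedicated rows.
#' @param planted_ccis Optional data frame (`source`, `target`, `pair`)
#'   of interactions to plant via [plant_lr_signal()].
#' @param lr_effect Multiplier for planted ligand/receptor genes
#'   (default 8).
#' @param lr_baseline_factor Baseline expression of ligand/receptor genes
#'   relative to the transcriptome bulk (default 0.25). Signalling genes
#'   are modelled as lowly expressed outside their active context so that
#'   an absolute score threshold can separate active from inactive
#'   complexes, as it does on real data.
#' @param seed Integer seed; the whole dataset is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 1000L, n_genes = 2000L, n_clusters = 3L,
                           proportions = NULL, baseline_mean = 1,
                           dispersion = 0.3, de_strength = 8,
                           markers_per_cluster = 40L, lridb = NULL,
                           planted_ccis = NULL, lr_effect = 8,
                           lr_baseline_factor = 0.25, seed = 1L) {
  if (is.null(proportions)) {
    proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(proportions) != n_clusters) {
    stop("proportions must have one entry per cluster", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  lr_genes <- character()
  if (!is.null(lridb)) {
    stopifnot(inherits(lridb, "lridb_table"))
    lr_genes <- unique(unlist(lapply(lridb$pairs, function(p) {
      c(p$ligand, p$receptor)
    })))
  }
  if (n_clusters * markers_per_cluster + length(lr_genes) > n_genes) {
    stop("more marker genes requested than genes available", call. = FALSE)
  }
  if (de_strength < 1) {
    stop("de_strength must be >= 1", call. = FALSE)
  }
  if (lr_effect <= 1) stop("lr_effect must be > 1", call. = FALSE)
  if (!is.null(planted_ccis) && is.null(lridb)) {
    stop("planted_ccis requires an lridb", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      n_clusters = as.integer(n_clusters), proportions = proportions,
      baseline_mean = baseline_mean, dispersion = dispersion,
      de_strength = de_strength,
      markers_per_cluster = as.integer(markers_per_cluster),
      lridb = lridb, planted_ccis = planted_ccis, lr_effect = lr_effect,
      lr_baseline_factor = lr_baseline_factor,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Simulate counts with planted cluster structure
#'
#' Draws negative-binomial counts (size = 1/dispersion) around gene-level
#' baseline means; each cluster over-expresses its own disjoint marker-gene
#' block by `de_strength`. Deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `X` (genes x cells count matrix, dimnames set),
#'   `labels` (integer cluster id per cell, 1-based), and `marker_genes`
#'   (list of marker row names per cluster).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    g <- spec$n_genes
    k <- spec$n_clusters
    counts_per_cluster <- diff(round(cumsum(c(0, spec$proportions)) * n))
    if (any(counts_per_cluster <= 0)) {
      stop("every cluster must receive at least one cell", call. = FALSE)
    }
    labels <- rep(seq_len(k), counts_per_cluster)
    # gene-level baseline means: log-normal spread around baseline_mean
    base_mu <- spec$baseline_mean * exp(stats::rnorm(g, sd = 0.5))
    mu <- matrix(base_mu, nrow = g, ncol = n)
    marker_genes <- vector("list", k)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * spec$markers_per_cluster + 1L):(j * spec$markers_per_cluster)
      cols <- which(labels == j)
      mu[rows, cols] <- mu[rows, cols] * spec$de_strength
      marker_genes[[j]] <- rows
    }
    gene_names <- sprintf("G%05d", seq_len(g))
    lr_genes <- character()
    if (!is.null(spec$lridb)) {
      lr_genes <- unique(unlist(lapply(spec$lridb$pairs, function(p) {
        c(p$ligand, p$receptor)
      })))
      lr_rows <- k * spec$markers_per_cluster + seq_along(lr_genes)
      gene_names[lr_rows] <- lr_genes
      # signalling genes sit below the transcriptome bulk at baseline
      mu[lr_rows, ] <- spec$baseline_mean * spec$lr_baseline_factor
      if (!is.null(spec$planted_ccis)) {
        for (r in seq_len(nrow(spec$planted_ccis))) {
          p <- spec$lridb$pairs[[spec$planted_ccis$pair[r]]]
          src_cells <- labels == spec$planted_ccis$source[r]
          tgt_cells <- labels == spec$planted_ccis$target[r]
          lig_rows <- lr_rows[match(p$ligand, lr_genes)]
          rec_rows <- lr_rows[match(p$receptor, lr_genes)]
          mu[lig_rows, src_cells] <- mu[lig_rows, src_cells] * spec$lr_effect
          mu[rec_rows, tgt_cells] <- mu[rec_rows, tgt_cells] * spec$lr_effect
        }
      }
    }
    size <- 1 / spec$dispersion
    X <- matrix(
      stats::rnbinom(g * n, size = size, mu = as.vector(mu)),
      nrow = g, ncol = n
    )
    rownames(X) <- gene_names
    colnames(X) <- sprintf("CELL%05d", seq_len(n))
    names(marker_genes) <- sprintf("cluster%d", seq_len(k))
    marker_genes <- lapply(marker_genes, function(r) gene_names[r])
    list(X = X, labels = labels, marker_genes = marker_genes,
         lr_genes = lr_genes)
  })
}

#' Generate a toy ligand-receptor table over synthetic gene symbols
#'
#' Ligand symbols are `LG####`, receptor symbols `RG####`; a stated fraction
#' of pairs get a two-subunit ligand or receptor so multi-subunit handling is
#' exercised.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param multi_subunit_frac Fraction of pairs with a two-subunit side.
#' @param species `"human"` or `"mouse"`.
#' @param seed Integer seed.
#' @return An `lridb_table`.
#' @export
make_toy_lridb <- function(n_pairs, multi_subunit_frac = 0.3,
                           species = "human", seed = 1L) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  if (multi_subunit_frac < 0 || multi_subunit_frac > 1) {
    stop("multi_subunit_frac must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_multi <- round(multi_subunit_frac * n_pairs)
    is_multi <- rep(FALSE, n_pairs)
    if (n_multi > 0) is_multi[sample.int(n_pairs, n_multi)] <- TRUE
    # each pair draws from its own symbol block, so keys are always unique
    pairs <- lapply(seq_len(n_pairs), function(i) {
      lig <- sprintf("LG%04d", i)
      rec <- sprintf("RG%04d", i)
      if (is_multi[i]) {
        if (stats::runif(1) < 0.5) {
          lig <- c(lig, sprintf("LG%04dB", i))
        } else {
          rec <- c(rec, sprintf("RG%04dB", i))
        }
      }
      lr_pair(lig, rec, species = species, sources = "synthetic")
    })
    new_lridb_table(pairs, species)
  })
}

#' Plant ligand-receptor signal into a simulated dataset
#'
#' For each planted interaction, multiplies the ligand-subunit genes by
#' `effect` in the source-cluster cells and the receptor-subunit genes by
#' `effect` in the target-cluster cells. All other entries are untouched, so
#' the planted triples are the unambiguous ground truth for
#' significance-labelling recovery tests.
#'
#' @param X Genes x cells matrix whose rownames cover the pair subunits.
#' @param labels Integer cluster label per cell (1-based).
#' @param lridb An `lridb_table` whose pairs index into `planted$pair`.
#' @param planted Data frame with columns `source`, `target`, `pair`
#'   (cluster ids and pair index into `lridb`).
#' @param effect Multiplier (> 0); 1 leaves `X` unchanged.
#' @return The modified matrix.
#' @export
plant_lr_signal <- function(X, labels, lridb, planted, effect) {
  stopifnot(inherits(lridb, "lridb_table"))
  if (effect <= 0) stop("effect must be positive", call. = FALSE)
  if (!all(c("source", "target", "pair") %in% names(planted))) {
    stop("planted must have columns source, target, pair", call. = FALSE)
  }
  k <- max(labels)
  for (r in seq_len(nrow(planted))) {
    src <- planted$source[r]
    tgt <- planted$target[r]
    idx <- planted$pair[r]
    if (src < 1 || src > k || tgt < 1 || tgt > k) {
      stop(sprintf("planted row %d references an unknown cluster", r),
           call. = FALSE)
    }
    if (idx < 1 || idx > length(lridb$pairs)) {
      stop(sprintf("planted row %d references an unknown pair", r),
           call. = FALSE)
    }
    p <- lridb$pairs[[idx]]
    miss <- setdiff(c(p$ligand, p$receptor), rownames(X))
    if (length(miss) > 0L) {
      stop(sprintf("planted pair %d has subunits absent from X: %s",
                   idx, paste(miss, collapse = ", ")), call. = FALSE)
    }
    X[p$ligand, labels == src] <- X[p$ligand, labels == src] * effect
    X[p$receptor, labels == tgt] <- X[p$receptor, labels == tgt] * effect
  }
  X
}

#' Write a synthetic stand-in for the curated ligand-receptor database
#'
#' The curated multi-subunit ligand-receptor database this package is built
#' around is distributed as supplementary material of its source publication
#' and is not redistributable here. This generator writes a deterministic
#' SYNTHETIC stand-in with the documented composition -- 5127 human and 4623
#' mouse pairs, a mix of single- and multi-subunit complexes, and
#' source/evidence annotations -- so that loading, deduplication, and
#' counting behaviour can be exercised end to end. The gene symbols are
#' synthetic; the table carries no biological content.
#'
#' @param path Output TSV path.
#' @param n_human,n_mouse Pair counts per species.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
write_synthetic_lridb <- function(path, n_human = 5127L, n_mouse = 4623L,
                                  seed = 20230923L) {
  dbs <- c("dbA", "dbB", "dbC", "dbD", "dbE")
  gen_species <- function(n, species) {
    style <- if (species == "human") toupper else function(x) {
      paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
    }
    n_multi <- round(0.25 * n)
    is_multi <- c(rep(TRUE, n_multi), rep(FALSE, n - n_multi))
    is_multi <- sample(is_multi)
    rows <- vapply(seq_len(n), function(i) {
      lig <- style(sprintf("sl%04d", i))
      rec <- style(sprintf("sr%04d", i))
      if (is_multi[i]) {
        if (i %% 2 == 0) {
          lig <- paste0(lig, "+", style(sprintf("sl%04db", i)))
        } else {
          rec <- paste0(rec, "+", style(sprintf("sr%04db", i)))
        }
      }
      src <- paste(sample(dbs, sample(1:3, 1)), collapse = ",")
      ev <- sprintf("PM%06d", sample.int(999999L, 1))
      paste(lig, rec, species, src, ev, sep = "\t")
    }, "")
    rows
  }
  with_seed(seed, {
    lines <- c(
      "ligand\treceptor\tspecies\tsource\tevidence",
      gen_species(n_human, "human"),
      gen_species(n_mouse, "mouse")
    )
    writeLines(lines, path)
  })
  invisible(path)
}
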