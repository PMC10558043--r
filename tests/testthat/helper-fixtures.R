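# Small fixtures shared across test files; everything is generated in code.

# A tiny valid ligand-receptor TSV on disk; returns the path.
write_toy_lridb_tsv <- function(path = tempfile(fileext = ".tsv"),
                                extra_rows = character()) {
  writeLines(c(
    "ligand\treceptor\tspecies\tsource\tevidence",
    "TGFB1\tTGFBR1+TGFBR2\thuman\tdbA\tPM000001",
    "NAMPT\tITGA5+ITGB1\thuman\tdbA,dbB\tPM000002",
    "MIF\tCD74+CD44\thuman\tdbB\t",
    "Tgfb1\tTgfbr1+Tgfbr2\tmouse\tdbA\tPM000003",
    extra_rows
  ), path)
  path
}

# A small dense expression matrix with named genes/cells.
toy_expression <- function(n_genes = 10, n_cells = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells)
    rownames(X) <- sprintf("G%03d", seq_len(n_genes))
    colnames(X) <- sprintf("C%03d", seq_len(n_cells))
    X
  })
}

# A planted-interaction world shared by scoring tests: 3 clusters of 150
# cells, 30 toy pairs, 12 planted triples at effect 8.
planted_world <- function(seed_db = 2, seed_planted = 42, seed_sim = 3) {
  db <- make_toy_lridb(30, multi_subunit_frac = 0.3, seed = seed_db)
  planted <- withr::with_seed(seed_planted, data.frame(
    source = sample(3, 12, replace = TRUE),
    target = sample(3, 12, replace = TRUE),
    pair = sample(30, 12)
  ))
  spec <- synthetic_spec(
    n_cells = 450, n_genes = 300, n_clusters = 3, markers_per_cluster = 10,
    lridb = db, planted_ccis = planted, lr_effect = 8, seed = seed_sim
  )
  sim <- simulate_counts(spec)
  list(db = db, planted = planted, spec = spec, sim = sim,
       Xn = normalize_log(qc_filter(sim$X)))
}

# Planted-truth array aligned to a (possibly filtered) table's pair order.
planted_truth_array <- function(tensor, db_full, db_used, planted) {
  key <- function(tbl) vapply(tbl$pairs, cellcrosstalk:::canonical_key, "")
  truth <- array(FALSE, dim(tensor$significant))
  idx <- match(key(db_full)[planted$pair], key(db_used))
  ok <- !is.na(idx)
  truth[cbind(planted$source[ok], planted$target[ok], idx[ok])] <- TRUE
  truth
}

# Exact one-sided (greater) rank-sum p-value by enumerating all splits.
exact_wilcoxon_greater <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  splits <- utils::combn(n, length(x))
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

# Definitional pair-counting ARI: the "together in both" count a and
# "apart in both" count b come from an O(n^2) loop over item pairs; the
# chance correction uses the permutation-model expectation and maximum of
# the rand index computed from the cluster-size marginals.
ari_pair_counting <- function(la, lb) {
  n <- length(la)
  same_a <- outer(la, la, "==")[upper.tri(diag(n))]
  same_b <- outer(lb, lb, "==")[upper.tri(diag(n))]
  a_pairs <- sum(same_a & same_b)
  b_pairs <- sum(!same_a & !same_b)
  c2 <- function(x) x * (x - 1) / 2
  total <- c2(n)
  ri <- (a_pairs + b_pairs) / total
  sum_a <- sum(c2(table(la))); sum_b <- sum(c2(table(lb)))
  e_a <- sum_a * sum_b / total
  max_a <- (sum_a + sum_b) / 2
  e_ri <- (2 * e_a + total - sum_a - sum_b) / total
  max_ri <- (2 * max_a + total - sum_a - sum_b) / total
  if (max_ri == e_ri) return(1)
  (ri - e_ri) / (max_ri - e_ri)
}

# All set partitions of seq_len(n) as label vectors.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (j in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, j)
  }
  out
}
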