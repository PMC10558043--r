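test_that("complex summaries and probabilities follow the product model", {
  expect_equal(complex_expression(c(2, 8)), 4)
  expect_equal(complex_expression(5), 5)
  expect_equal(complex_expression(c(3, 0, 9)), 0)  # any silent subunit kills it
  expect_error(complex_expression(c(1, -2)), "non-negative")
  expect_error(complex_expression(numeric()), "non-empty")

  expect_equal(interaction_probability(4, 3), 12)
  expect_equal(interaction_probability(0, 99), 0)
  expect_equal(interaction_probability(2.5, 7), interaction_probability(7, 2.5))
  # single-subunit complexes reduce the model to a plain mean product
  l <- c(1.2, 3.4); r <- c(0.7, 2.2)
  expect_equal(interaction_probability(complex_expression(mean(l)),
                                       complex_expression(mean(r))),
               mean(l) * mean(r))
})

test_that("the regularized product score has its documented boundary behavior", {
  expect_equal(lrscore(0, 0, mu = 1), 0)
  expect_equal(lrscore(2, 2, mu = 2), 0.5)  # sqrt(lr) == mu
  expect_error(lrscore(1, 1, mu = 0), "positive")
  grid <- seq(0, 5, by = 0.25)
  s <- vapply(grid, function(l) lrscore(l, 3, mu = 1.5), 0)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s < 1))
})

test_that("majority vote needs two of exactly three votes", {
  expect_true(majority_vote(c(TRUE, TRUE, FALSE)))
  expect_false(majority_vote(c(TRUE, FALSE, FALSE)))
  expect_true(majority_vote(c(TRUE, TRUE, TRUE)))
  expect_error(majority_vote(c(TRUE, FALSE)), "three")
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  v <- c(TRUE, FALSE, TRUE)
  for (p in perms) expect_true(majority_vote(v[p]))
})

test_that("permutation engine matches exhaustive enumeration on a 12-cell toy", {
  X <- withr::with_seed(4, matrix(rpois(2 * 12, 3) + 0.0, 2, 12,
                                  dimnames = list(c("L", "R"), paste0("c", 1:12))))
  labels <- rep(1:2, each = 6)
  pair <- list(ligand = "L", receptor = "R", source = 1, target = 2)
  # exact null: the statistic depends only on which cells form cluster 1
  obs <- mean(X["L", 1:6]) * mean(X["R", 7:12])
  splits <- utils::combn(12, 6)
  exact_stats <- apply(splits, 2, function(idx) {
    mean(X["L", idx]) * mean(X["R", -idx])
  })
  p_exact <- mean(exact_stats >= obs)
  p_mc <- permutation_pvalue(X, labels, pair, "mean-product",
                             n_perm = 4000, seed = 11)
  expect_lt(abs(p_mc - p_exact), 0.03)
  # bounds of the add-one estimator
  expect_gte(p_mc, 1 / 4001)
  expect_lte(p_mc, 1)
})

test_that("permutation p-values hit their boundary cases", {
  X <- matrix(c(rep(0, 10), rpois(10, 5)), 2, 10, byrow = TRUE,
              dimnames = list(c("L", "R"), paste0("c", 1:10)))
  labels <- rep(1:2, each = 5)
  pair <- list(ligand = "L", receptor = "R", source = 1, target = 2)
  # absent ligand: observed statistic 0, no permutation can be beaten
  expect_equal(permutation_pvalue(X, labels, pair, n_perm = 99, seed = 1), 1)
  # planted strong signal: p at the estimator's floor
  X2 <- toy_expression(4, 200, seed = 8) + 0.0
  rownames(X2)[1:2] <- c("L", "R")
  lab2 <- rep(1:2, each = 100)
  X2["L", lab2 == 1] <- X2["L", lab2 == 1] * 10
  X2["R", lab2 == 2] <- X2["R", lab2 == 2] * 10
  p <- permutation_pvalue(X2, lab2, pair, "mean-product", n_perm = 1000,
                          seed = 2)
  expect_lte(p, 0.01)
  expect_error(permutation_pvalue(X, rep(1, 10), pair), "two clusters")
})

test_that("scaling a source cluster scales ligand-side probabilities linearly", {
  w <- planted_world()
  db_f <- filter_pairs_to_genes(w$db, rownames(w$Xn))
  t1 <- label_significant(w$Xn, w$sim$labels, db_f, n_perm = 10, seed = 1)
  X2 <- w$Xn
  X2[, w$sim$labels == 1] <- X2[, w$sim$labels == 1] * 3
  t2 <- label_significant(X2, w$sim$labels, db_f, n_perm = 10, seed = 1)
  k <- which(vapply(db_f$pairs, function(p)
    length(p$ligand) == 1 && length(p$receptor) == 1, NA))[1]
  expect_equal(t2$probability[1, 2, k], 3 * t1$probability[1, 2, k])
  expect_equal(t2$probability[2, 3, k], t1$probability[2, 3, k])
})

test_that("significance labelling recovers planted interactions", {
  w <- planted_world()
  db_f <- filter_pairs_to_genes(w$db, rownames(w$Xn))
  tensor <- label_significant(w$Xn, w$sim$labels, db_f, n_perm = 500, seed = 4)
  truth <- planted_truth_array(tensor, w$db, db_f, w$planted)
  tp <- sum(tensor$significant & truth)
  fp <- sum(tensor$significant & !truth)
  fn <- sum(!tensor$significant & truth)
  expect_gte(2 * tp / (2 * tp + fp + fn), 0.9)
  # structure: probability is exactly the product of complex summaries,
  # p-values live in (0, 1], significance is the 2-of-3 vote
  expect_true(all(tensor$probability >= 0))
  expect_true(all(tensor$pval_mean > 0 & tensor$pval_mean <= 1))
  expect_identical(tensor$significant, tensor$votes >= 2L)
  # determinism
  tensor2 <- label_significant(w$Xn, w$sim$labels, db_f, n_perm = 500, seed = 4)
  expect_identical(tensor, tensor2)
})

test_that("a silent ligand yields zero probability and no significance", {
  X <- toy_expression(6, 40, seed = 5) + 0.0
  rownames(X)[1:3] <- c("LZ", "RZ", "LOK")
  X["LZ", ] <- 0
  db <- cellcrosstalk:::new_lridb_table(
    list(lr_pair("LZ", "RZ"), lr_pair("LOK", "RZ")), "human"
  )
  labels <- rep(1:2, each = 20)
  tensor <- label_significant(X, labels, db, n_perm = 50, seed = 6)
  expect_true(all(tensor$probability[, , 1] == 0))
  expect_false(any(tensor$significant[, , 1]))
  expect_error(
    label_significant(X, labels,
                      cellcrosstalk:::new_lridb_table(list(), "human")),
    "no ligand-receptor pairs"
  )
})

test_that("long-format export preserves the tensor layout", {
  w <- planted_world()
  db_f <- filter_pairs_to_genes(w$db, rownames(w$Xn))
  tensor <- label_significant(w$Xn, w$sim$labels, db_f, n_perm = 20, seed = 9)
  df <- as.data.frame(tensor)
  expect_equal(nrow(df), 3 * 3 * length(db_f$pairs))
  i <- 57
  expect_equal(
    df$probability[i],
    tensor$probability[df$source_cluster[i], df$target_cluster[i],
                       match(paste0(df$ligand[i], "->", df$receptor[i]),
                             tensor$pair_names)]
  )
  expect_identical(df$significant, df$votes >= 2)
})
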