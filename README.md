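# cellcrosstalk

Cell–cell interaction (CCI) inference from single-cell RNA-seq data, for
researchers who want both an unsupervised view of their tissue's cluster
structure and a ranked, statistically labelled catalogue of the
ligand–receptor (L–R) signals passing between those clusters.

## What it computes

**Clustering.** Cells are clustered by a jointly trained autoencoder and
graph convolutional network over a K-nearest-neighbour cell graph. The GCN
propagates through the normalized adjacency
Â = D̃<sup>−1/2</sup>(A + I)D̃<sup>−1/2</sup>, and the two branches are fused
layer by layer, Z̃<sup>(l)</sup> = (1−ε)Z<sup>(l)</sup> + εH<sup>(l)</sup>.
Soft assignments come from a Student's-t kernel around trainable centers,

> q<sub>ij</sub> = (1 + ‖h<sub>i</sub> − μ<sub>j</sub>‖²/v)<sup>−(v+1)/2</sup> / Σ<sub>j′</sub> (…),

sharpened by the self-training target
p<sub>ij</sub> = (q²<sub>ij</sub>/f<sub>j</sub>) / Σ<sub>j′</sub>(q²<sub>ij′</sub>/f<sub>j′</sub>),
and trained with L = α·KL(P‖Q) + β·KL(P‖Z) + L<sub>res</sub>
(α = 10⁻⁴, β = 10⁻³). The cluster number, when unknown, comes from Louvain
community detection on the cell graph.

**Interaction scoring.** For source cluster i, target cluster j and pair k,

> P<sub>ij</sub><sup>k</sup> = L<sub>i</sub> · R<sub>j</sub>,

where each complex summary is the geometric mean of its subunits'
10%-truncated cluster means — a silent subunit inactivates the complex.
Pairs are labelled significant by majority vote of three scorers: a
regularized product score √(lr)/(μ + √(lr)) ≥ 0.5, and two permutation
tests (plain and truncated mean products) at p ≤ 0.01.

**Supervised re-prediction.** A residual MLP over SVD-reduced per-cell
complex expression, fused by row-wise dot product with a GCN over the
top-200 L–R pair correlation graph (|corr| ≥ τ = 0.95), trained with focal
loss under stratified 5-fold cross-validation.

Multi-subunit complexes are first-class throughout: the L–R table dialect
writes them as `ITGA5+ITGB1`, and deduplication works on sorted subunit
sets per side.

## Worked example

A label-free run on a generated dataset with five planted clusters and
sixteen planted L–R signals (this is exactly what `scripts/acceptance.R`
executes; numbers below are its output at `--seed 1`):

```r
library(cellcrosstalk)

db <- make_toy_lridb(60, multi_subunit_frac = 0.25, seed = 112648)
planted <- local({  # 16 planted (source, target, pair) triples
  set.seed(217377)
  data.frame(source = sample(5, 16, TRUE), target = sample(5, 16, TRUE),
             pair = sample(60, 16))
})
spec <- synthetic_spec(n_cells = 750, n_genes = 400, n_clusters = 5,
                       de_strength = 8, markers_per_cluster = 20,
                       lridb = db, planted_ccis = planted,
                       lr_effect = 8, seed = 322106)
sim <- simulate_counts(spec)

Xn    <- normalize_log(qc_filter(sim$X))
Xh    <- select_hvg(Xn, min(2000L, nrow(Xn)))
pc    <- prcomp(t(Xh), rank. = 50, center = TRUE)$x
graph <- build_knn_graph(pc, K = 10)
k     <- estimate_n_clusters(graph, seed = 426835)   # -> 5
fit   <- fit_cluster_model(Xh, graph, n_clusters = k, seed = 1,
                           dims = c(128L, 32L),
                           pretrain_epochs = 150L, epochs = 50L)
adjusted_rand_index(fit$labels, sim$labels)          # -> 1

db_f   <- filter_pairs_to_genes(db, rownames(Xn))
tensor <- label_significant(Xn, fit$labels, db_f, n_perm = 500, seed = 1)
sum(tensor$significant)                              # -> 98

lr_graph <- build_lr_pair_graph(tensor, top_n = 60, tau = 0.95)
feats    <- build_cci_features(Xn, fit$labels, db_f, tensor,
                               nodes = lr_graph$nodes, d = 32)
cv <- train_interaction_model(feats, lr_graph, folds = 5, seed = 1,
                              epochs = 150)
mean(cv$metrics$auc)                                 # -> 0.790
```

Reading the numbers: Louvain finds the five planted clusters and the joint
model reproduces the planted partition exactly (ARI 1). The majority vote
flags 98 (source, target, pair) triples: the 16 planted signals plus their
one-sided "cross" triples — a planted ligand concentrated in one source
cluster beats the diluted permutation null against *any* target, which is
an inherent (and real) property of one-sided product permutation tests at
this cluster count. The classifier then re-predicts those majority-vote
labels from held-out cluster pairs with mean cross-validated AUC 0.79;
on worlds with more cluster-pair samples (the acceptance suite uses
6 × 6 cluster pairs and 200 pairs) it reaches AUC ≥ 0.9.

The long-format interaction table (`as.data.frame(tensor)`) has one row
per (source cluster, target cluster, pair) with the probability, the three
scorer outputs, the vote count, and the significance flag.

## Command line

A thin wrapper over the same functions:

```sh
./exec/cellcrosstalk simulate --out-dir data --seed 1
./exec/cellcrosstalk cluster  --config run.json --seed 1
./exec/cellcrosstalk score    --config run.json --seed 1
./exec/cellcrosstalk train    --config run.json --seed 1
./exec/cellcrosstalk viz      --config run.json
```

`run.json` holds any `cci_config()` fields; flags override it. Outputs are
plain CSV/JSON (labels, embedding, interactions, CV metrics, plot-ready
bubble/chord/heatmap/network tables), and every run writes the config it
ran with, which is sufficient to reproduce it byte for byte.

## Acceptance script

`scripts/acceptance.R` regenerates a planted dataset from `--seed`, runs
the full label-free pipeline (clustering → scoring → classifier
cross-validation), logs the recovered cluster count, ARI, significant
triples and CV AUC, and writes the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
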