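# motgnn

Binary disease classification from multi-omics data with tree-generated
feature graphs, graph-embedded neural encoders, and built-in
interpretability.

## The problem

Studies that profile the same patients across several molecular layers —
DNA methylation, mRNA expression, miRNA expression — face three
obstacles at once: far more features than samples, strong heterogeneity
between layers, and the absence of reliable interaction networks to
structure the feature space. Similarity-based graphs (Pearson, cosine)
are sensitive to arbitrary thresholds and blind to task-specific,
nonlinear relationships; flat concatenation of layers drowns
modality-specific signal; and most deep models offer no account of
*which* features or *which* omics layer drove a prediction.

`motgnn` addresses this with a supervised, modality-specific pipeline:

1. **Tree-generated graphs.** For each modality `X_i` (samples x `p_i`),
   a gradient-boosted tree ensemble (default 100 trees) is trained
   against the binary labels `Y`. The union of features used in any
   split defines a reduced feature set of size `p_i* < p_i`, and every
   direct parent–child pair of split features contributes an undirected
   edge. Self-loops are added, giving a sparse augmented adjacency
   `Ã_i` over the selected features. A random-forest backend
   (`motgnn_rf`) provides the graph-generation ablation.
2. **Graph-embedded encoders.** Each modality is encoded by a network
   whose first hidden layer has width `p_i*` and computes

   `Z_1 = σ( X* (W_in ⊙ Ã) + b_in )`,  σ = ReLU,

   with the Hadamard product re-applied at every forward pass, so
   connections absent from the graph are structurally inert. Dense
   layers (with batch normalization and dropout) follow, yielding an
   embedding `Z_i` per modality.
3. **Fusion classifier.** The embeddings are concatenated,
   `Z = Z_1 | Z_2 | Z_3`, and passed through a feedforward layer and a
   2-unit softmax head. Training minimizes binary cross-entropy plus an
   L2 penalty (`λ Σ w²`) with mini-batch Adam and early stopping on a
   validation split.
4. **Interpretability without post-hoc tooling.** Feature importance is
   the connection-weights score
   `IF_j = Σ_u |W_in[j,u]| · 1(Ã[j,u] = 1)` (row sums of the absolute
   masked input weights); the relative importance of each omics layer is
   `RIG_i = ‖W_{Zi↔f}‖₁ / Σ_k ‖W_{Zk↔f}‖₁`, where `W_{Zi↔f}` is the
   fusion weight block attached to `Z_i`. The three `RIG_i` sum to 1.

Evaluation follows a repeated stratified protocol: 60/20/20
train/validation/test splits, stratified by class and repeated (default
20 times) with per-repeat seeds; accuracy, ROC-AUC and F1 are reported
as mean ± SD with a normal-approximation 95% CI. Normalization (min-max
to [0,1]) and graph construction are fitted on the training split of
each repeat, so no information leaks from validation or test samples.

A synthetic-data module generates three heterogeneous modalities
(bimodal methylation-like, right-skewed expression-like, zero-inflated
miRNA-like) with a controllable class ratio and a planted set of
informative features, so the whole pipeline is testable without any
download.

## Worked example

```r
library(motgnn)

cfg <- synthetic_config(n_samples = 200, class_ratio = 0.25,
                        dims = c(60, 60, 30),
                        informative_per_modality = c(8, 8, 4),
                        effect_size = 2, noise_sd = 0.5, seed = 1001)
res <- run_experiment(cfg,
                      cfg = training_config(learning_rate = 1e-3),
                      scheme = split_scheme(n_repeats = 5, base_seed = 1))
res
#> <motgnn_experiment> motgnn, 5 repeats
#>   accuracy 1.000 +/- 0.000 [1.000, 1.000]
#>   roc_auc  1.000 +/- 0.000 [1.000, 1.000]
#>   f1       1.000 +/- 0.000 [1.000, 1.000]
#>   mean RIG: 0.339 / 0.330 / 0.330
```

A 3:1 imbalanced but well-separated synthetic dataset is classified
perfectly on every held-out test split (an all-majority classifier
would score F1 = 0 here), and the three omics layers — which carry
comparable planted signal — receive near-equal relative importances.
Per-repeat metrics, confusion counts and graph statistics are in
`res$per_repeat` and `res$graph_stats`; ranked biomarkers come from
`importance_report()` / `top_k_biomarkers()`.

The same pipeline runs from the shell:

```sh
motgnn simulate --config sim.yaml --outdir data/
motgnn run --meth data/meth.tsv --mrna data/mrna.tsv \
           --mirna data/mirna.tsv --labels data/labels.tsv \
           --repeats 20 --seed 42 --outdir results/
motgnn explain --checkpoint results/checkpoint --top-k 30
```

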