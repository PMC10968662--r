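# driverGCN

Personalized cancer driver gene prioritization from multi-omics data with
a graph convolutional network (GCN) and a conditional random field (CRF)
refinement layer.

## What it does, and for whom

Cohort-level driver callers rank one gene list for a whole cancer type.
`driverGCN` is for analysts who need *per-patient* candidate driver genes:
it builds one interaction subnetwork per patient — the protein–protein
interaction (PPI) subgraph induced on that patient's mutated genes united
with the cohort's differentially expressed genes (DEGs) — takes the
disjoint union across patients so every node is a (sample, gene) pair,
and scores each node's probability of being a driver gene in that patient.

Node features concatenate three blocks, min-max normalized to [0, 1]:

- **molecular (4):** the node's mutation status, log2 expression,
  methylation beta value, and GISTIC2 copy-number category;
- **system-level (18):** global gene properties (gene length, domain
  count, gene age, essentiality, ...);
- **structural (d = 20):** node2vec embeddings of the union graph.

The model is a two-layer GCN over the self-looped, symmetrically
normalized adjacency `A_hat = D~^(-1/2)(A + I)D~^(-1/2)`:

    H1 = ReLU(A_hat X W1)
    H  = CRF(H1)                  # attention-weighted mean-field refinement
    h  = sigmoid(A_hat H W2)

The CRF layer pulls each embedding toward an attention-weighted average of
its neighbors while staying anchored to its GCN embedding,

    H_i <- (alpha Q_i + beta * sum_j g_ij H_j) / (alpha + beta * sum_j g_ij),

with GAT-style coefficients `g_ij = softmax_j att(Wt H_i, Wt H_j)`, and the
corresponding energy `sum_i alpha||H_i - Q_i||^2 + beta sum_j g_ij ||H_i - H_j||^2`
joins the classification loss: `l_total = l_CRF + l_theta`, where `l_theta`
is a binary cross-entropy whose positive class is up-weighted by a factor
`p >= 1` against class imbalance. Training is Adam (lr 0.001, weight decay
0.005, dropout 0.1, 3000 epochs by default) with optional grid search by
stratified 5-fold cross-validation. All gradients are analytic and checked
numerically in the test suite.

A synthetic cohort generator with planted driver signal
(`simulate_cohort()`) makes the whole pipeline runnable and testable with
no external downloads.

## Worked example

```r
library(driverGCN)

sim <- sim_config(seed = 1L)                 # 20 samples x 300 genes, 30 drivers
cfg <- dg_config(epochs = 500L, seed = 1L)
run <- run_pipeline(sim, cfg)

run$model
#> GCN-CRF driver-gene model
#>   features: 42  hidden: 64  CRF: alpha=1 beta=1 T=2
#>   trained 500 epochs (lr 0.001, weight decay 0.005, dropout 0.1, positive weight 1)
#>   loss: 1.2396 -> 0.4387 (l_crf 0.0239, l_theta 0.4148 at last epoch)

run$report$metrics
#>     set       acc       auc      aupr
#> 1 train 0.8295964 0.9328856 0.9647985
#> 2  test 0.9038462 0.9128289 0.9610994

head(run$result$per_sample$S001, 3)
#>    gene     score rank
#> 1 G0105 0.9263193    1
#> 2 G0172 0.9112669    2
#> 3 G0217 0.9068507    3
```

The test metrics are computed on held-out nodes whose *genes* were never
seen in training (the default split is stratified over genes); a test AUC
of 0.91 means the model recovers planted drivers it was not trained on. Each
sample's ranked list is that patient's candidate driver genes; top-k
overlap against a reference catalogue, per-sample hit counts and
rare-driver flags (< 2% cohort mutation frequency) are in
`run$report`.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/driverGCN.R simulate --out data/ --seed 1
Rscript inst/cli/driverGCN.R run --data data/ --work work/ --seed 1
```

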