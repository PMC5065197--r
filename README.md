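# nmfpost

Unsupervised discovery of molecular cancer subtypes from nonnegative gene
expression matrices, using nonnegative matrix factorization (NMF) with a
normalization post-processing step, an embedded gene filter, and
consensus-based selection of the number of subtypes.

## The problem and the method

Given a nonnegative expression matrix *A* (*n* genes × *m* samples), basic
NMF finds *W* (*n* × *k*, the **metagenes**) and *H* (*k* × *m*, per-sample
metagene expression) minimizing the generalized Kullback–Leibler divergence

    L(A, WH) = Σᵢⱼ [ Aᵢⱼ log(Aᵢⱼ / (WH)ᵢⱼ) − Aᵢⱼ + (WH)ᵢⱼ ],

which is maximum-likelihood estimation under independent Poisson
observations Aᵢⱼ ~ Poisson((WH)ᵢⱼ). Sample *j* is assigned to the cluster
*i* whose *hᵢⱼ* is largest in column *j*.

The decomposition is only defined up to a positive diagonal rescaling:
*WH = (WD⁻¹)(DH)* for any positive diagonal *D*, and different runs can land
on different scalings, so the raw argmax assignment is not unique. The
post-processing step picks one representative by a column statistic of *W*:
with the **maximum norm**, each column of *W* is divided by its largest
entry and the matching row of *H* is multiplied by it (`W′ = WD⁻¹`,
`H′ = DH`, `Dⱼ = max Wⱼ`). The product — and hence the fit — is unchanged,
but the assignment becomes invariant to the rescaling ambiguity, and the
entries of *W′* fall in [0, 1] and read as gene-in-metagene memberships.
Seven alternative statistics (1/2/3-norms, standard deviation, 0.95/0.75/0.5
quantiles) are provided for comparison.

On top of this sit:

* an **embedded gene filter**: genes whose membership spread
  `uᵢ = maxⱼ W′ᵢⱼ − minⱼ W′ᵢⱼ` is at or below the median (or another
  quantile) of all spreads are uninformative about subtype structure and
  are removed, after which NMF is refit on the kept genes;
* **rank selection**: for each candidate *k*, many seeded runs are
  summarized in a consensus matrix (average co-clustering frequency); the
  cophenetic correlation between the consensus-derived distances and an
  average-linkage dendrogram of them measures stability, and the most
  stable *k* is recommended;
* an **evaluation protocol**: permutation-matched clustering accuracy
  (Hungarian matching of predicted clusters to true classes), repeated
  seeded runs summarized as mean ± SEM, and paired two-sided t-tests
  between method configurations;
* a **Poisson synthetic-data generator** planting known metagenes, cluster
  labels, and a configurable fraction of irrelevant (flat-membership)
  genes, so the whole pipeline can be exercised and scored without any
  external dataset.

## Worked example

```r
library(nmfpost)

sim <- simulate_expression(n_signal = 300, n_irrelevant = 100, m = 24, k = 3,
                           expression_scale = 20, dominance = 3, seed = 11)
sim
#> Simulated expression: 400 genes (100 irrelevant) x 24 samples, k = 3
#>   scale 20, dominance 3, seed 11

cl <- post_process_cluster(sim$A, k = 3, seed = 1, scheme = "max",
                           filter = "embedded")
cl
#> NMF clustering: k = 3, scheme = max, filter = embedded, seed = 1
#> cluster
#> 1 2 3
#> 8 8 8
cl$filter_report
#> embedded filter: kept 200 / 400 genes (threshold 0.7567)

clustering_accuracy(cl$labels, sim$true_labels)
#> [1] 100

scan <- select_k(sim$A, k_range = 2:5, nloop = 10, base_seed = 1)
as.data.frame(scan)
#>   k cophenetic
#> 1 2  0.9766030
#> 2 3  1.0000000
#> 3 4  0.9993809
#> 4 5  0.9987642
recommended_k(scan)
#> [1] 3
```

The 24 samples are recovered in three balanced clusters of 8 (100%
accuracy against the planted labels); the embedded filter removes the 200
genes with the smallest membership spread — which includes essentially all
planted irrelevant genes — and the cophenetic correlation peaks at the
planted rank *k* = 3.

Result objects carry broom-style `tidy()` / `glance()` methods and ggplot2
`autoplot()` methods (consensus heatmap, cophenetic-versus-rank curve,
per-seed accuracy boxplots). A command-line interface is installed as
`exec/nmfpost` with subcommands `simulate`, `fit`, `cluster`, `select-k`,
and `evaluate`.

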