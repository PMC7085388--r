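# roughkm

Rough K-means ambiguity filtering for tabular disease classification.

Clinical tables routinely contain records whose measurements show traits
of both the diseased and the healthy class. These records sit between the
class clusters, are the ones classifiers most often get wrong, and
distort the decision boundary when trained on. `roughkm` finds them
*without looking at the labels* and quantifies what excluding them buys a
classifier.

The core is **rough K-means**, a soft clustering in which each cluster is
an interval set: a *lower approximation* of certain members and an *upper
approximation* of possible ones. After computing the distances from an
object *x* to all centroids, let *i* be the nearest cluster and form the
tie set

    T = { j ≠ i : d(x, c_j) / d(x, c_i) ≤ ε }          (ε = 1.4 by default)

If *T* is empty, *x* belongs certainly to cluster *i*; otherwise *x* lies
in the **boundary region** of cluster *i* and of every cluster in *T* —
it is *ambiguous*. Centroids update as a weighted blend
`w_lower · mean(lower) + w_upper · mean(boundary)` (0.7/0.3 by default).
The ambiguity filter excludes the boundary-region records before a
stratified 70/30 split and the training of four reference classifiers
(Gaussian naive Bayes, RBF-kernel SVM, K-nearest neighbours, random
forest); a paired report shows accuracy, sensitivity, specificity,
precision and F1 with and without the exclusion.

For validation the package generates synthetic tables with *planted*
ambiguity: two Gaussian classes plus a seeded fraction of rows
re-positioned at the inter-class midpoint, labels kept, so boundary
detection can be scored against ground truth.

## Worked example

```r
library(roughkm)

# 600 records, 15% planted in the class-overlap region
sim <- simulate_overlap_data(n_per_class = 300, overlap_fraction = 0.15,
                             seed = 11)

fit <- rough_kmeans(sim$dataset$X, rkm_params(k = 2, threshold = 1.4,
                                              seed = 11))
fit
#> Rough partition: 600 objects, 2 clusters
#>   lower approximations: 540 objects (278 + 262)
#>   boundary region: 60 ambiguous objects
#>   converged: yes after 11 iterations

ambiguity_recall(fit, sim$truth)
#> [1] 0.6666667

report <- run_experiment(sim$dataset, experiment_config(
  preprocess = NULL, rkm = rkm_params(seed = 11), split_seed = 11))
report
#> Paired classification experiment
#>   rough partition: 540 lower / 60 boundary (filter stage: before_split)
#>   naive_bayes    baseline  92.78%  filtered  99.38%  (+6.60)
#>   svm_rbf        baseline  92.78%  filtered  98.15%  (+5.37)
#>   knn            baseline  95.00%  filtered  99.38%  (+4.38)
#>   random_forest  baseline  93.89%  filtered  99.38%  (+5.49)
```

Reading the numbers: the clustering flags 60 of 600 records as boundary
objects (the planted fraction was 90; two-thirds of them are caught along
with almost nothing else). The baseline arm trains and scores on all
records; the filtered arm excludes the 60 ambiguous ones before the same
70/30 split. Every classifier gains several accuracy points because its
errors concentrate exactly in the overlap region that was removed. The
partition counts, per-arm confusion tables and configuration echo are in
the returned report object (`report_table()`, `write_report()`).

Real CSV tables enter through `load_dataset()` (schemas for the common
diabetes, kidney and breast-cancer benchmark tables, plus `generic`) and
`preprocess_dataset()` (median/mode imputation, nominal encoding, min-max
scaling). A thin command-line wrapper is installed as `exec/roughkm` with
`fit`, `simulate` and `experiment` subcommands.

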