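# tumorconnectome

Graph-network ("connectomic") analysis of lesions on co-registered
multiparametric radiological images, for imaging scientists who want to
quantify intra-tumoral heterogeneity beyond texture statistics.

Tumors are mosaics of microenvironments. This package models a lesion as a
complex network whose nodes are the ROI voxels and whose edges link voxels
with similar multiparametric intensity *signatures*: for voxel $(i,j)$ the
signature is $x_{ij} \in \mathbb{R}^D$, one normalized intensity per
imaging channel (e.g. T1 post-contrast, T2, ADC). Edges follow a
$k$-nearest-neighbour or distance-threshold rule on the pairwise Euclidean
matrix; shortest-path (geodesic) distances along the graph approximate
distances on the intensity manifold. Each lesion is then summarized by
size-normalized network metrics —

* degree centrality $\deg(i)/(n-1)$, node strength, eigenvector centrality,
* betweenness centrality (weighted paths, normalized by $(n-1)(n-2)/2$),
* local clustering coefficient,
* per-component average path length (APL), and
* the number of connected components, a proxy for the number of distinct
  tissue habitats —

and cohorts are classified by **IsoSVM**: an Isomap embedding of the metric
vectors (classical MDS of graph geodesics) followed by a linear SVM with
inverse-frequency class penalties, tuned by grid search under leave-one-out
cross-validation. Group contrasts and classifier scores are evaluated with
Welch t-tests, the Matthews correlation coefficient, rank-based AUC-ROC and
average-precision AUC-PR with stratified bootstrap confidence intervals.
Networks can be rendered back onto the anatomic image as edge/node
overlays, and a seeded multiparametric phantom generator makes the whole
pipeline testable without clinical data. Homogeneous "benign-like" phantoms
and heterogeneous multi-habitat "malignant-like" phantoms reproduce the
qualitative signature of lesion aggressiveness: lower connectivity, more
components and longer path lengths in the heterogeneous class.

## Worked example

```r
library(tumorconnectome)

# a heterogeneous 4-cluster phantom lesion on a 64x64 3-channel slice
ph <- generate_phantom(malignant_phantom_spec(seed = 7))
cx <- lesion_connectome(ph$image, ph$mask, seed = 1)
cx$summary
#> <connectome_summary> n_nodes = 377 | components = 2
#>      degree_centrality betweenness_centrality eigenvector_centrality
#>                 0.0173                 0.0063                 0.0204
#> clustering_coefficient    average_path_length          node_strength
#>                 0.4758                 0.1915                 0.0115
```

The lesion's 377 voxels form a graph that splits into 2 components (two
intensity habitats), with low degree centrality — each voxel connects to
only ~1.7% of the others — and a mean within-component geodesic of 0.19 in
normalized intensity units.

```r
cohort <- generate_cohort(10, seed = 42)            # 10 benign + 10 malignant
cc <- cohort_connectomes(cohort, seed = 7)
compare_groups(cc$features[, c("degree_centrality", "average_path_length")],
               cc$labels, positive = "malignant")
#>                metric mean_negative mean_positive      p_value auc_roc
#> 1   degree_centrality    0.03722624    0.01753718 1.709872e-05       1
#> 2 average_path_length    0.13115190    0.20851658 4.354274e-03       1

fit <- fit_isosvm(feature_table(cc$features, cc$labels), seed = 3)
eval_report(fit$cv$scores, fit$cv$truth, predictions = fit$cv$predictions,
            positive = "malignant", n_boot = 500, seed = 5)
#> <eval_report> positive = malignant (n = 10 vs 10)
#>   MCC     1.000
#>   AUC-ROC 1.000 (95% CI 1.000-1.000)
#>   AUC-PR  1.000 (95% CI 1.000-1.000)
#>   sens/spec at threshold: 1.000 / 1.000
```

Benign-like phantoms show roughly double the degree centrality and clearly
shorter path lengths ($p < 0.005$ at 10 + 10), and the IsoSVM separates the
two classes perfectly under leave-one-out CV — as designed: phantom class
contrasts are set well above the noise floor so the machinery, not the
data, is what is being tested.

Overlays (`render_overlay()`, or `tcf.R viz` from the command line) draw
the surviving neighborhood-graph edges and metric-colored nodes over any
loaded channel and write deterministic PNG/SVG files.

A thin CLI covering the whole chain lives at `inst/cli/tcf.R`
(`simulate`, `build`, `viz`, `run`); `run_pipeline()` /
`tcf.R run --config run.yaml` executes simulate → build → metrics →
classify → evaluate → render and writes an MD5 manifest whose checksums
reproduce exactly under a fixed config.

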