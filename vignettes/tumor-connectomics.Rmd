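---
title: "Voxel-graph connectomics of multiparametric lesions: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-graph connectomics of multiparametric lesions: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorconnectome)
```

## The model

A lesion on co-registered multiparametric imaging is treated as a complex
network. Every voxel inside the region of interest contributes a *tissue
signature*: the vector of its intensities across the $D$ imaging channels
(for instance T1 post-contrast, T2 and an ADC map), each channel min–max
normalized to $[0,1]$ in double precision. Voxels are the nodes; two voxels
are linked when their signatures are close in feature space, either because
one is among the $k$ nearest neighbours of the other (`mode = "knn"`, the
default) or because their Euclidean distance is below a threshold $t$
(`mode = "threshold"`). Edge weights are the raw Euclidean feature
distances, and shortest-path (*geodesic*) distances along the graph
approximate distances on the underlying intensity manifold — the same
construction that underlies Isomap.

The network is summarized by six node-level maps, averaged into one global
vector per lesion:

* **degree centrality** $\deg(i)/(n-1)$ and **node strength** (sum of edge
  affinities $1 - w/w_{\max}$, divided by $n-1$) — connectivity;
* **betweenness centrality**, weighted shortest-path mediation normalized by
  $(n-1)(n-2)/2$ — bottleneck structure;
* **eigenvector centrality**, the principal eigenvector of the binarized
  adjacency of the largest component, unit Euclidean norm — hub structure;
* **clustering coefficient**, the triangle density around each node —
  local cohesion;
* **local average path length (APL)**, the mean geodesic distance to the
  nodes *reachable* from each node.

The voxel graph of a heterogeneous lesion is usually *not* connected; a
naive APL would be infinite. APL is therefore computed per component, and
the **number of connected components** is reported as its own global metric
— a proxy for the number of distinct tissue microenvironments ("habitats").

All centralities are normalized by functions of $n$ so lesions of different
sizes are comparable. This is deliberate and has a visible consequence:
with a $k$-NN rule the raw degree is always about $k$, so degree centrality
of a small homogeneous lesion is genuinely larger than that of a big one.
Size is part of the biology being summarized, not a nuisance parameter.

### Binarized vs weighted: which metric uses which

Degree, eigenvector centrality and clustering use the **binarized** edge
set, which keeps them in $[0,1]$ regardless of intensity scale. Path-based
quantities — geodesics, APL, the paths inside betweenness — use the
**Euclidean edge weights**, which keeps them metric. Node strength bridges
the two via the affinity transform $a = 1 - w/w_{\max}$ (all affinities 1
when $w_{\max}=0$); a raw-weight alternative would leave the unit interval,
which is why the affinity form is the default.

## Classification: IsoSVM

The per-lesion metric vectors are classified by an Isomap-embedded SVM.
Features are standardized (zero mean, unit variance on the training rows;
constant features pass through centered), a $k$-NN graph over the *rows* is
built, geodesics are computed, and classical multidimensional scaling of
the squared geodesics (double centering, top eigenvectors scaled by
$\sqrt{\lambda}$) gives the embedded coordinates. A linear SVM with
per-class misclassification penalties (inverse class frequency
$n/(2n_c)$ times the base cost $C$) is trained on the embedding. The
Isomap step supplies the nonlinearity, so the SVM itself can stay linear.

Hyperparameters — `embed_k` in {4, 6, 8}, `embed_dim` in {2, 3, 4}, `C` in
{0.1, 1, 10} — are tuned by grid search under leave-one-out
cross-validation. Each fold re-standardizes and re-embeds from its $n-1$
training rows only, and places the held-out row by a Nyström-style
out-of-sample extension (geodesics to training rows approximated through
the row's `embed_k` nearest training neighbours, then the MDS projection
formula). A training row re-embedded this way reproduces its own
coordinates, which the tests assert. The selected grid point maximizes
LOOCV *balanced* accuracy — robust to the class imbalance the per-class
penalties address — with deterministic tie-breaks (smaller `embed_dim`,
then smaller `C`, then smaller `embed_k`); plain accuracy is available via
`criterion = "accuracy"`.

Two classes that are well separated in feature space produce a
*disconnected* row graph at any small `embed_k`. The standalone
`isomap_embed()` treats that as an error (naming the smallest connecting
$k$), because a silent repair would surprise anyone using it as a manifold
learner. Inside `fit_isosvm()` the row graph is instead bridged through the
closest cross-component pairs (`connect = "augment"`): cross-class geodesics
become long but finite, the embedding keeps the classes far apart, and the
fit proceeds. This is the one place the package deliberately departs from
textbook Isomap, and it is what lets cleanly separable cohorts be fitted at
all.

SVM decision values, oriented so that larger means the positive (second)
class, are the continuous scores fed to ROC and precision–recall analysis.

## Evaluation statistics

Group contrasts use Welch's unequal-variance two-sided t-test (group
spreads of real lesion cohorts differ substantially, so the pooled form is
not assumed; if both groups are constant with equal means the convention
$p = 1$ applies). Classifier scores are summarized by the Matthews
correlation coefficient (zero-denominator convention: 0), the rank-based
(Mann–Whitney) AUC-ROC with ties counted one half, and AUC-PR as average
precision with step integration — trapezoids on a PR curve systematically
overestimate the area, so they are not used. Confidence intervals are
percentile bootstrap over 2000 stratified resamples by default (resampling
within class keeps every resample two-class), seeded and therefore
reproducible. The operating point for sensitivity/specificity, when hard
predictions are not supplied, maximizes Youden's J along the ROC with ties
resolved toward the smaller threshold.

## The phantom generator

`generate_phantom()` builds a single-slice (64×64 by default),
three-channel lesion: a disk of radius $r$ whose voxels take per-cluster
channel means plus Gaussian noise (SD 0.05), clipped to $[0,1]$; the
spatial cluster layout is a seeded Voronoi partition of the disk, i.e.
spatially coherent habitats without imposed radial symmetry. Defaults for
the two classes:

* **benign-like** (`benign_phantom_spec()`): radius 7, one intensity
  cluster, cross-channel noise correlation 0.85. A homogeneous lesion is
  one tissue type whose channels co-vary through a single latent factor
  (density/partial volume), so its signature cloud is nearly
  one-dimensional — which is also what gives it a well-knit, high-clustering
  graph.
* **malignant-like** (`malignant_phantom_spec()`): radius 11, four clusters
  arranged as two habitat *pairs* (`make_cluster_means()`): habitat centers
  8 noise-SDs apart, so the voxel graph reliably splits into separate
  components, while the two clusters within a habitat sit 3.2 noise-SDs
  apart, close enough that their tails bridge through a sparse neck that
  stretches path lengths. Channel correlation is 0.3.

Cluster means must be at least 3 noise-SDs apart (enforced) so the class
structure is real rather than a noise artifact; the homogenizing follow-up
transform of responder phantoms is the one sanctioned exception. Cohorts
(`generate_cohort()`) derive one sub-seed per subject, shift all cluster
means jointly by a per-subject N(0, 0.02) offset (joint, so the separations
are preserved exactly) and jitter the radius by at most one voxel.
Longitudinal pairs shrink responders (radius ×0.6) and pull their cluster
means toward the centroid (contrast ×0.3), while non-responders keep
geometry and contrast; scan noise is redrawn at follow-up either way.

What the phantoms emulate: multiparametric intensity contrast, habitat
structure, class imbalance in size, longitudinal homogenization. What they
do not: MRI physics (coil profiles, bias fields, partial volume, k-space
artifacts), spatially correlated noise, registration error, irregular
lesion shapes, and the overlap of real benign/malignant intensity
distributions. Passing tests on phantoms therefore demonstrate that the
machinery measures what it claims to measure under a known ground truth —
not that clinical effect sizes or clinical classification accuracy would be
reproduced.

## Numerical choices and degenerate inputs

* Exact-duplicate signatures keep their own nodes and produce zero-weight
  edges, preserving voxel-count semantics; geodesics handle zero weights
  exactly, and betweenness (whose path search requires strictly positive
  weights) nudges them by `min(w > 0) * 1e-9`, far below any real feature
  distance.
* Eigenvector centrality iterates the shifted matrix $A + I$, which is
  primitive on a connected component, so bipartite components (trees,
  paths) converge too; tolerance 1e-10, at most 10000 iterations, explicit
  absolute value fixes the Perron sign. An edgeless graph yields zeros with
  a warning.
* All ties break deterministically (smaller index, smaller slice, smaller
  hyperparameter), so outputs are bit-stable and the pipeline manifest
  checksums reproduce.
* k-NN symmetrization is by union (an edge if either endpoint proposes
  it) — the convention that keeps graphs best connected; intersection is
  available via `neighborhood_spec(symmetrize = "intersection")`.
* The default `k = 5` is intentionally small: components carry information
  here, and a large `k` would weld habitats together. `k` is always
  recorded in provenance.
* Normalization is per-channel min–max over the whole image by default
  (reproducible across mask revisions); `within_mask` restricts the
  reference range to an ROI where acquisition ranges differ wildly.
  Signatures contain intensities only; `include_xy = TRUE` can append
  scaled coordinates for experimentation, but spatial position is otherwise
  kept for visualization alone.
* Masks larger than `subsample_cap` (default 2000 voxels) are uniformly
  subsampled with a recorded seed: the distance matrix and all-pairs
  geodesics are quadratic and cubic in the node count, and 2000 nodes keep
  a lesion's build in the seconds range without visibly moving the global
  metric means.
* The renderer rasterizes everything itself and writes pixels through
  `png::writePNG`, so identical inputs give byte-identical files; numeric
  color-bar labels live in the SVG sidecar, where text is a primitive.

## Problem sizes used by the checks

The test-suite properties run on 200 random graphs of up to 12 nodes
(against brute-force oracles: Floyd–Warshall, path-count betweenness,
triangle counting, dense `eigen()`, union-find), 50 weighted graphs of up
to 50 nodes for the geodesic cross-check, phantom cohorts of 20 + 20
subjects and longitudinal arms of 10 + 10 pairs — sizes at which the
independent oracles are exact and the stochastic contrasts are stable
across seeds.

## Known limitations

* All-pairs geodesics are exact, never approximated; very large ROIs rely
  on the subsampling cap rather than landmark or streaming schemes.
* The classifier is strictly two-class.
* The out-of-sample embedding is an interpolation; rows far outside the
  training cloud are extrapolated and their embedding degrades gracefully
  but unavoidably.
* Overlay rendering is 2D (slice-based); 3D graphs export as edge lists
  for external viewers.
* No multiple-testing correction is applied across the per-metric t-tests;
  the metric family is small and fixed, and the group tables report raw
  p-values.
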