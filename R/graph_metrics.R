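# Node-level network maps and per-lesion summaries.
#
# Centralities and the clustering coefficient are computed on the binarized
# edge set so they stay in [0, 1]; path-based quantities (betweenness paths,
# geodesic path lengths) use the Euclidean edge weights so the geodesics stay
# metric. All centralities are size-normalized (degree and strength by n - 1,
# betweenness by (n-1)(n-2)/2) so lesions of different voxel counts are
# comparable.

TCF_METRICS <- c("degree_centrality", "betweenness_centrality",
                 "eigenvector_centrality", "clustering_coefficient",
                 "average_path_length", "node_strength")

node_map <- function(name, values, coords = NULL) {
  structure(list(metric_name = name, values = as.double(values),
                 node_coords = coords),
            class = "node_metric_map")
}

#' @export
print.node_metric_map <- function(x, ...) {
  cat("<node_metric_map>", x$metric_name, "| n =", length(x$values),
      "| range =", paste(signif(range(x$values), 4), collapse = ".."), "\n")
  invisible(x)
}

#' Degree centrality per node
#'
#' Fraction of possible neighbors each node connects to: `deg(i) / (n - 1)`
#' on the binarized edge set.
#'
#' @param graph A [build_graph()] result.
#' @return A `node_metric_map`.
#' @export
degree_centrality <- function(graph) {
  n <- graph$n_nodes
  deg <- tabulate(c(graph$edges$i, graph$edges$j), nbins = n)
  node_map("degree_centrality", deg / (n - 1), graph$node_coords)
}

#' Betweenness centrality per node
#'
#' Fraction of weighted shortest paths between other node pairs that pass
#' through each node, with fractional counting over equal-length paths,
#' normalized by `(n-1)(n-2)/2`. Graphs with fewer than 3 nodes score zero
#' everywhere.
#'
#' @inheritParams degree_centrality
#' @return A `node_metric_map`.
#' @export
betweenness_centrality <- function(graph) {
  n <- graph$n_nodes
  if (n < 3L || nrow(graph$edges) == 0L) {
    return(node_map("betweenness_centrality", rep(0, n), graph$node_coords))
  }
  w <- graph$edges$w
  if (any(w == 0)) {
    # Dijkstra needs positive weights; nudge exact-duplicate edges by an
    # amount far below any real feature distance so path structure is kept
    eps <- if (any(w > 0)) min(w[w > 0]) * 1e-9 else 1
    w[w == 0] <- eps
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  btw <- igraph::betweenness(g, weights = w, normalized = FALSE)
  node_map("betweenness_centrality", btw / ((n - 1) * (n - 2) / 2),
           graph$node_coords)
}

#' Eigenvector centrality per node
#'
#' Principal eigenvector of the binarized adjacency matrix of the largest
#' connected component (ties broken toward the component containing the
#' smallest node index), nonnegative and scaled to unit Euclidean norm;
#' nodes outside that component score 0. Computed by power iteration to
#' tolerance 1e-10 (at most 10000 iterations).
#'
#' @inheritParams degree_centrality
#' @return A `node_metric_map`.
#' @export
eigenvector_centrality <- function(graph) {
  n <- graph$n_nodes
  vals <- rep(0, n)
  if (nrow(graph$edges) == 0L) {
    warning("edgeless graph: eigenvector centrality is zero everywhere")
    return(node_map("eigenvector_centrality", vals, graph$node_coords))
  }
  g <- as_igraph(graph)
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  big <- which(sizes == max(sizes))[1]  # igraph labels components by first
  idx <- which(memb == big)             # member, so [1] is the lowest-index tie
  A <- matrix(0, length(idx), length(idx))
  pos <- match(seq_len(n), idx)
  ei <- pos[graph$edges$i]; ej <- pos[graph$edges$j]
  keep <- !is.na(ei) & !is.na(ej)
  A[cbind(ei[keep], ej[keep])] <- 1
  A[cbind(ej[keep], ei[keep])] <- 1
  v <- rep(1 / sqrt(length(idx)), length(idx))
  for (it in seq_len(10000L)) {
    nv <- A %*% v + v   # shifted iteration (A + I): primitive on a connected
    nrm <- sqrt(sum(nv^2))   # component, so bipartite graphs converge too
    if (nrm == 0) break
    nv <- as.vector(nv) / nrm
    if (max(abs(nv - v)) < 1e-10) { v <- nv; break }
    v <- nv
  }
  vals[idx] <- abs(v)  # Perron vector is nonnegative; fix sign explicitly
  node_map("eigenvector_centrality", vals, graph$node_coords)
}

#' Local clustering coefficient per node
#'
#' Fraction of each node's neighbor pairs that are themselves connected
#' (binarized graph): `2 T(i) / (deg(i)(deg(i) - 1))`, and 0 when
#' `deg(i) < 2`.
#'
#' @inheritParams degree_centrality
#' @return A `node_metric_map`.
#' @export
clustering_coefficient <- function(graph) {
  n <- graph$n_nodes
  if (nrow(graph$edges) == 0L) {
    return(node_map("clustering_coefficient", rep(0, n), graph$node_coords))
  }
  g <- as_igraph(graph)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0
  node_map("clustering_coefficient", cc, graph$node_coords)
}

#' Local average path length per node
#'
#' Mean geodesic distance from each node to the nodes reachable from it
#' (same connected component). Computing the mean per component sidesteps the
#' infinite path lengths a disconnected network would otherwise produce; the
#' number of components is reported alongside as its own metric. Nodes in
#' singleton components score 0.
#'
#' @param geo A [geodesic_matrix()] result.
#' @param node_coords Optional coordinates for overlay.
#' @return A `node_metric_map`.
#' @export
local_average_path_length <- function(geo, node_coords = NULL) {
  gm <- geo$g
  n <- nrow(gm)
  vals <- vapply(seq_len(n), function(i) {
    gi <- gm[i, -i]
    gi <- gi[is.finite(gi)]
    if (length(gi) == 0L) 0 else mean(gi)
  }, numeric(1))
  node_map("average_path_length", vals, node_coords)
}

#' Node strength per node
#'
#' Edge weights (feature distances) are turned into affinities
#' `a = 1 - w / w_max` (`w_max` = largest edge weight in the graph; all
#' affinities are 1 when `w_max = 0`), and each node scores the sum of its
#' incident affinities divided by `n - 1`, giving a \[0, 1\] similarity-weighted
#' connectivity.
#'
#' @inheritParams degree_centrality
#' @return A `node_metric_map`.
#' @export
node_strength <- function(graph) {
  n <- graph$n_nodes
  if (nrow(graph$edges) == 0L) {
    return(node_map("node_strength", rep(0, n), graph$node_coords))
  }
  wmax <- max(graph$edges$w)
  aff <- if (wmax == 0) rep(1, nrow(graph$edges)) else 1 - graph$edges$w / wmax
  s <- rep(0, n)
  for (e in seq_along(aff)) {
    s[graph$edges$i[e]] <- s[graph$edges$i[e]] + aff[e]
    s[graph$edges$j[e]] <- s[graph$edges$j[e]] + aff[e]
  }
  node_map("node_strength", s / (n - 1), graph$node_coords)
}

#' Number of connected components ("clusters")
#'
#' The count of disjoint subgraphs of the tumor network, used as a global
#' metric: a proxy for the number of distinct tissue microenvironments.
#'
#' @param geo A [geodesic_matrix()] result.
#' @return Integer component count.
#' @export
count_components <- function(geo) {
  length(unique(geo$component_id))
}

#' Per-lesion connectome summary
#'
#' Means of the six node-level maps plus the component count: the global
#' feature vector used for group comparison and classification.
#'
#' @param graph A [build_graph()] result.
#' @param geo The matching [geodesic_matrix()]; computed when missing.
#' @param provenance Optional named list recorded with the summary.
#' @return A `connectome_summary`: list with `metrics` (named numeric of the
#'   six metric means), `n_components`, `n_nodes`, `spec` and `provenance`.
#' @export
summarize_connectome <- function(graph, geo = NULL, provenance = list()) {
  stopifnot(inherits(graph, "tumor_graph"))
  if (is.null(geo)) geo <- geodesic_matrix(graph)
  m <- c(degree_centrality = mean(degree_centrality(graph)$values),
         betweenness_centrality = mean(betweenness_centrality(graph)$values),
         eigenvector_centrality = mean(eigenvector_centrality(graph)$values),
         clustering_coefficient = mean(clustering_coefficient(graph)$values),
         average_path_length = mean(local_average_path_length(geo)$values),
         node_strength = mean(node_strength(graph)$values))
  structure(list(metrics = m,
                 n_components = count_components(geo),
                 n_nodes = graph$n_nodes,
                 spec = graph$spec,
                 provenance = provenance),
            class = "connectome_summary")
}

#' @export
print.connectome_summary <- function(x, ...) {
  cat("<connectome_summary> n_nodes =", x$n_nodes,
      "| components =", x$n_components, "\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Flatten a connectome summary to a named numeric vector
#'
#' @param x A `connectome_summary`.
#' @param include_components Append `n_components` (default `TRUE`).
#' @export
as_feature_vector <- function(x, include_components = TRUE) {
  v <- x$metrics
  if (include_components) v <- c(v, n_components = as.numeric(x$n_components))
  v
}

#' Longitudinal change in connectome metrics (delta-TCF)
#'
#' Fractional change of every summary metric between a baseline and a
#' follow-up study: `(followup - baseline) / baseline` (multiply by 100 for
#' percent). Metrics whose baseline value is exactly 0 are flagged as
#' undefined and excluded rather than propagated as NaN.
#'
#' @param baseline,followup `connectome_summary` objects for the two
#'   timepoints.
#' @return A `delta_tcf` object: list with `delta` (named fractional changes
#'   over the defined metrics) and `undefined` (names of excluded metrics).
#' @export
delta_tcf <- function(baseline, followup) {
  b <- as_feature_vector(baseline)
  f <- as_feature_vector(followup)
  stopifnot(identical(names(b), names(f)))
  ok <- b != 0
  structure(list(delta = (f[ok] - b[ok]) / b[ok],
                 undefined = names(b)[!ok]),
            class = "delta_tcf")
}

#' @export
print.delta_tcf <- function(x, ...) {
  cat("<delta_tcf> percent change:\n")
  print(round(100 * x$delta, 2))
  if (length(x$undefined)) {
    cat("undefined (baseline = 0):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write node metric maps back into image space
#'
#' Places each node's metric value at its voxel coordinate in a zero
#' background, for overlay or NIfTI export.
#'
#' @param map A `node_metric_map` whose `node_coords` are set (0-based).
#' @param shape Integer grid dimensions.
#' @return Numeric array of dimension `shape`.
#' @export
map_to_volume <- function(map, shape) {
  if (is.null(map$node_coords)) stop_tcf("map has no node coordinates", class = "tcf_spec_error")
  vol <- array(0, dim = shape)
  vol[map$node_coords + 1L] <- map$values
  vol
}
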