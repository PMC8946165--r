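#' Neighborhood rule for linking tissue signatures
#'
#' Two voxels are linked either when one is among the `k` nearest feature-space
#' neighbors of the other (`mode = "knn"`) or when their feature distance is at
#' most `t` (`mode = "threshold"`).
#'
#' @param mode `"knn"` or `"threshold"`.
#' @param k Neighbor count (knn mode). The default `k = 5` is deliberately
#'   small so that heterogeneous lesions fall apart into several components,
#'   which is itself an informative metric.
#' @param t Closeness threshold in feature-distance units (threshold mode).
#' @param symmetrize For knn mode, `"union"` (edge when either endpoint
#'   proposes it; default, the usual Isomap convention) or `"intersection"`.
#' @return A `neighborhood_spec` object.
#' @export
neighborhood_spec <- function(mode = c("knn", "threshold"), k = 5L, t = NULL,
                              symmetrize = c("union", "intersection")) {
  mode <- match.arg(mode)
  symmetrize <- match.arg(symmetrize)
  if (mode == "knn") {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop_tcf("k must be a positive integer", class = "tcf_spec_error")
    t <- NULL
  } else {
    if (is.null(t) || !is.finite(t) || t <= 0) {
      stop_tcf("threshold t must be > 0", class = "tcf_spec_error")
    }
    k <- NULL
  }
  structure(list(mode = mode, k = k, t = t, symmetrize = symmetrize),
            class = "neighborhood_spec")
}

#' Pairwise Euclidean distance matrix over tissue signatures
#'
#' @param sig A [extract_signatures()] result, or a numeric matrix with one
#'   signature per row.
#' @return A symmetric n x n matrix of class `euclidean_matrix` with zero
#'   diagonal, computed in double precision.
#' @export
euclidean_matrix <- function(sig) {
  x <- if (inherits(sig, "tissue_signatures")) sig$features else as.matrix(sig)
  if (nrow(x) < 2L) stop_tcf("need at least 2 signatures", class = "tcf_spec_error")
  if (!all(is.finite(x))) stop_tcf("non-finite feature values", class = "tcf_data_error")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- NULL
  class(d) <- c("euclidean_matrix", class(d))
  d
}

#' Build the voxel network from a distance matrix
#'
#' In knn mode every node proposes edges to its `k` nearest neighbors
#' (self excluded; distance ties broken toward the smaller node index) and the
#' graph is the symmetrized union (or intersection) of the proposals. In
#' threshold mode an edge joins every pair with distance at most `t`. Edge
#' weights are the raw Euclidean distances; exact-duplicate signatures yield
#' zero-weight edges and remain distinct nodes.
#'
#' @param d An [euclidean_matrix()] (or any symmetric distance matrix).
#' @param spec A [neighborhood_spec()].
#' @param node_coords Optional matrix of voxel coordinates carried along for
#'   visualization.
#' @return A `tumor_graph`: list with `n_nodes`, `edges` (data.frame `i`, `j`,
#'   `w` with `i < j`, 1-based), `node_coords` and `spec`.
#' @export
build_graph <- function(d, spec = neighborhood_spec(), node_coords = NULL) {
  d <- unclass(d)
  n <- nrow(d)
  if (is.null(n) || n != ncol(d)) stop_tcf("d must be square", class = "tcf_spec_error")
  if (spec$mode == "knn") {
    if (spec$k >= n) {
      stop_tcf("k = ", spec$k, " must be < number of nodes (", n, ")",
               class = "tcf_spec_error")
    }
    prop <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(d[i, -i], seq_len(n)[-i])   # ties -> smaller index first
      nb <- (seq_len(n)[-i])[ord[seq_len(spec$k)]]
      prop[i, nb] <- TRUE
    }
    adj <- if (spec$symmetrize == "union") prop | t(prop) else prop & t(prop)
  } else {
    adj <- d <= spec$t
    diag(adj) <- FALSE
  }
  sel <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      w = d[sel])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_nodes = n, edges = edges,
                 node_coords = node_coords, spec = spec),
            class = "tumor_graph")
}

#' @export
print.tumor_graph <- function(x, ...) {
  cat("<tumor_graph> n =", x$n_nodes, "| edges =", nrow(x$edges),
      "| mode =", x$spec$mode,
      if (x$spec$mode == "knn") paste0("(k=", x$spec$k, ")")
      else paste0("(t=", x$spec$t, ")"), "\n")
  invisible(x)
}

# igraph view of a tumor_graph (isolated nodes preserved)
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j),
                           weight = graph$edges$w)
  }
  g
}

#' Geodesic (shortest-path) distance matrix of a tumor graph
#'
#' All-pairs shortest-path distances along the weighted edges (Dijkstra from
#' every source), approximating distances on the underlying data manifold.
#' Pairs in different connected components are `Inf`.
#'
#' @param graph A [build_graph()] result.
#' @return A `geodesic_matrix`: list with `g` (n x n symmetric matrix, zero
#'   diagonal, `Inf` across components) and `component_id` (integer labels,
#'   numbered by the smallest member node).
#' @export
geodesic_matrix <- function(graph) {
  stopifnot(inherits(graph, "tumor_graph"))
  if (graph$n_nodes < 2L) stop_tcf("need at least 2 nodes", class = "tcf_spec_error")
  g <- as_igraph(graph)
  gm <- igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "dijkstra")
  dimnames(gm) <- NULL
  comp <- igraph::components(g)$membership
  structure(list(g = gm, component_id = as.integer(comp)),
            class = "geodesic_matrix")
}

#' Export a tumor graph as an edge-list CSV
#'
#' @param graph A `tumor_graph`.
#' @param path Output CSV path; columns `i`, `j`, `weight` (1-based indices).
#' @export
write_graph_csv <- function(graph, path) {
  df <- data.frame(i = graph$edges$i, j = graph$edges$j, weight = graph$edges$w)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
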