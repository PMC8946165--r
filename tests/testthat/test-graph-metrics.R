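complete_graph <- function(n, w = 1) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  manual_graph(n, data.frame(i = pairs[, 1], j = pairs[, 2], w = w))
}

test_that("degree centrality matches closed forms", {
  expect_equal(degree_centrality(complete_graph(4))$values, rep(1, 4))
  expect_equal(degree_centrality(manual_graph(3, data.frame(i = integer(0),
                                                            j = integer(0),
                                                            w = numeric(0))))$values,
               rep(0, 3))
  p4 <- manual_graph(4, data.frame(i = 1:3, j = 2:4, w = 1))
  expect_equal(degree_centrality(p4)$values, c(1, 2, 2, 1) / 3)
})

test_that("betweenness matches closed forms on complete and star graphs", {
  expect_equal(betweenness_centrality(complete_graph(5))$values, rep(0, 5))
  s4 <- manual_graph(4, data.frame(i = 1, j = 2:4, w = 1))
  # center mediates all 3 leaf pairs; normalization (n-1)(n-2)/2 = 3
  expect_equal(betweenness_centrality(s4)$values, c(1, 0, 0, 0))
})

test_that("eigenvector centrality matches symmetry closed forms", {
  expect_equal(eigenvector_centrality(complete_graph(3))$values,
               rep(1 / sqrt(3), 3), tolerance = 1e-9)
  star <- manual_graph(4, data.frame(i = 1, j = 2:4, w = 1))
  # K_{1,3}: center 1/sqrt(2), leaves 1/sqrt(6)
  expect_equal(eigenvector_centrality(star)$values,
               c(1 / sqrt(2), rep(1 / sqrt(6), 3)), tolerance = 1e-8)
})

test_that("eigenvector centrality lives on the lowest-labeled largest component", {
  # two equal triangles: component of node 1 wins the size tie
  g <- manual_graph(6, data.frame(i = c(1, 2, 1, 4, 5, 4),
                                  j = c(2, 3, 3, 5, 6, 6), w = 1))
  v <- eigenvector_centrality(g)$values
  expect_true(all(v[1:3] > 0))
  expect_equal(v[4:6], rep(0, 3))

  edgeless <- manual_graph(3, data.frame(i = integer(0), j = integer(0),
                                         w = numeric(0)))
  expect_warning(v0 <- eigenvector_centrality(edgeless))
  expect_equal(v0$values, rep(0, 3))
})

test_that("clustering coefficient counts triangles", {
  tri <- complete_graph(3)
  expect_equal(clustering_coefficient(tri)$values, rep(1, 3))
  star <- manual_graph(4, data.frame(i = 1, j = 2:4, w = 1))
  expect_equal(clustering_coefficient(star)$values, rep(0, 4))
  # K4 minus edge 1-2: nodes 1,2 have degree 2 and one closed pair -> 1;
  # nodes 3,4 have degree 3 and 2 of 3 pairs closed -> 2/3
  k4m <- manual_graph(4, data.frame(i = c(1, 1, 2, 2, 3),
                                    j = c(3, 4, 3, 4, 4), w = 1))
  expect_equal(clustering_coefficient(k4m)$values, c(1, 1, 2/3, 2/3))
})

test_that("local average path length honours reachability and singletons", {
  expect_equal(local_average_path_length(geodesic_matrix(complete_graph(6)))$values,
               rep(1, 6))
  p3 <- manual_graph(3, data.frame(i = 1:2, j = 2:3, w = 1))
  apl <- local_average_path_length(geodesic_matrix(p3))$values
  expect_equal(apl, c(1.5, 1, 1.5))
  expect_equal(mean(apl), 4 / 3)

  iso <- manual_graph(4, data.frame(i = c(1, 2, 1), j = c(2, 3, 3), w = 1))
  v <- local_average_path_length(geodesic_matrix(iso))$values
  expect_equal(v[4], 0)
  expect_equal(v[1:3], rep(1, 3))
})

test_that("node strength follows the affinity transform", {
  # triangle with weights 1, 2, 4: affinities 0.75, 0.5, 0
  tri <- manual_graph(3, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                    w = c(1, 2, 4)))
  expect_equal(node_strength(tri)$values, c(0.625, 0.375, 0.25))
  # every weight equal to the max -> all affinities zero
  expect_equal(node_strength(complete_graph(4, w = 2))$values, rep(0, 4))
  # isolated node scores zero
  g <- manual_graph(3, data.frame(i = 1, j = 2, w = 1))
  expect_equal(node_strength(g)$values[3], 0)
})

test_that("summaries are the arithmetic means of the node maps", {
  k4 <- complete_graph(4)
  s <- summarize_connectome(k4)
  expect_equal(unname(s$metrics["degree_centrality"]), 1)
  expect_equal(unname(s$metrics["clustering_coefficient"]), 1)
  expect_equal(unname(s$metrics["betweenness_centrality"]), 0)
  expect_equal(unname(s$metrics["average_path_length"]), 1)
  expect_identical(s$n_components, 1L)

  two_tri <- manual_graph(6, data.frame(i = c(1, 2, 1, 4, 5, 4),
                                        j = c(2, 3, 3, 5, 6, 6), w = 1))
  s2 <- summarize_connectome(two_tri)
  expect_identical(s2$n_components, 2L)
  expect_equal(unname(s2$metrics["degree_centrality"]), 2 / 5)
  expect_equal(unname(s2$metrics["clustering_coefficient"]), 1)

  g <- random_graph(10, p = 0.4, seed = 77)
  geo <- geodesic_matrix(g)
  s3 <- summarize_connectome(g, geo)
  expect_equal(unname(s3$metrics["degree_centrality"]),
               mean(degree_centrality(g)$values), tolerance = 1e-12)
  expect_equal(unname(s3$metrics["node_strength"]),
               mean(node_strength(g)$values), tolerance = 1e-12)
})

test_that("summaries are invariant under node relabeling", {
  g <- random_graph(9, p = 0.4, seed = 55)
  set.seed(56)
  perm <- sample(9)
  pe <- data.frame(i = perm[g$edges$i], j = perm[g$edges$j], w = g$edges$w)
  gp <- manual_graph(9, pe)
  s1 <- summarize_connectome(g)
  s2 <- summarize_connectome(gp)
  expect_equal(s1$metrics, s2$metrics, tolerance = 1e-9)
  expect_identical(s1$n_components, s2$n_components)
})

test_that("all six metrics agree with brute-force oracles on random graphs", {
  for (s in 1:25) {
    n <- sample(4:12, 1)
    g <- random_graph(n, p = 0.35, seed = 400 + s)
    geo <- geodesic_matrix(g)
    expect_lt(max(abs(degree_centrality(g)$values -
                        rowSums(graph_adjacency(g)) / (n - 1))), 1e-12)
    expect_lt(max(abs(betweenness_centrality(g)$values -
                        oracle_betweenness(g))), 1e-9)
    expect_lt(max(abs(clustering_coefficient(g)$values -
                        oracle_clustering(g))), 1e-12)
    expect_lt(max(abs(eigenvector_centrality(g)$values -
                        oracle_eigenvector(g))), 1e-8)
    expect_lt(max(abs(local_average_path_length(geo)$values -
                        oracle_local_apl(g))), 1e-9)
    expect_identical(count_components(geo), oracle_components(g))
  }
})

test_that("metric values stay in [0, 1] on arbitrary graphs", {
  for (s in 1:20) {
    g <- random_graph(sample(3:15, 1), p = runif(1, 0.1, 0.9), seed = 600 + s)
    for (f in list(degree_centrality, betweenness_centrality,
                   clustering_coefficient, node_strength)) {
      v <- suppressWarnings(f(g)$values)
      expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
    }
  }
})

test_that("delta-TCF computes fractional change and flags zero baselines", {
  g <- complete_graph(5)
  s <- summarize_connectome(g)
  d0 <- delta_tcf(s, s)
  expect_true(all(d0$delta == 0))

  sb <- s; sf <- s
  sb$metrics["degree_centrality"] <- 0.10
  sf$metrics["degree_centrality"] <- 0.15
  d <- delta_tcf(sb, sf)
  expect_equal(unname(d$delta["degree_centrality"]), 0.5)

  sb$metrics["betweenness_centrality"] <- 0
  d2 <- delta_tcf(sb, sf)
  expect_true("betweenness_centrality" %in% d2$undefined)
  expect_false("betweenness_centrality" %in% names(d2$delta))
  expect_equal(unname(d2$delta["degree_centrality"]), 0.5)
})

test_that("node maps write back into image space", {
  g <- complete_graph(3)
  g$node_coords <- rbind(c(0, 0), c(1, 1), c(2, 2))
  m <- degree_centrality(g)
  vol <- map_to_volume(m, c(4, 4))
  expect_equal(vol[1, 1], 1)
  expect_equal(vol[2, 2], 1)
  expect_equal(sum(vol), 3)
})
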