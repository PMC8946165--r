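# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package:
# Floyd-Warshall instead of Dijkstra, sigma-counting betweenness instead of
# Brandes, direct triangle counting, base eigen() instead of power iteration,
# union-find instead of graph traversal.

# Build a tumor_graph by hand from an edge table (bypasses build_graph).
manual_graph <- function(n, edges) {
  edges <- as.data.frame(edges)
  names(edges) <- c("i", "j", "w")[seq_len(ncol(edges))]
  if (is.null(edges$w)) edges$w <- 1
  sw <- edges$i > edges$j
  tmp <- edges$i[sw]; edges$i[sw] <- edges$j[sw]; edges$j[sw] <- tmp
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_nodes = as.integer(n), edges = edges,
                 node_coords = NULL, spec = neighborhood_spec("knn", k = 1)),
            class = "tumor_graph")
}

# seeded random weighted graph, edge probability p
random_graph <- function(n, p = 0.35, seed = 1, wmin = 0.1, wmax = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  manual_graph(n, data.frame(i = e[, 1], j = e[, 2],
                             w = runif(nrow(e), wmin, wmax)))
}

graph_weight_matrix <- function(graph) {
  n <- graph$n_nodes
  W <- matrix(Inf, n, n); diag(W) <- 0
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]; w <- graph$edges$w[e]
    W[i, j] <- min(W[i, j], w); W[j, i] <- W[i, j]
  }
  W
}

graph_adjacency <- function(graph) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  A[cbind(graph$edges$i, graph$edges$j)] <- 1
  A[cbind(graph$edges$j, graph$edges$i)] <- 1
  A
}

oracle_floyd_warshall <- function(graph) {
  D <- graph_weight_matrix(graph)
  n <- nrow(D)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# shortest-path counts + betweenness by Floyd-Warshall sigma counting
oracle_betweenness <- function(graph, tol = 1e-10) {
  D <- graph_weight_matrix(graph)
  n <- nrow(D)
  S <- (is.finite(D) & D > 0) * 1  # one shortest path per direct edge
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k) next
      for (j in seq_len(n)) {
        if (j == k || j == i) next
        alt <- D[i, k] + D[k, j]
        if (!is.finite(alt)) next
        if (alt < D[i, j] - tol) {
          D[i, j] <- alt
          S[i, j] <- S[i, k] * S[k, j]
        } else if (abs(alt - D[i, j]) <= tol) {
          S[i, j] <- S[i, j] + S[i, k] * S[k, j]
        }
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(D[s, t]) || S[s, t] == 0) next
        thr <- D[s, v] + D[v, t]
        if (is.finite(thr) && abs(thr - D[s, t]) <= tol) {
          btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_clustering <- function(graph) {
  A <- graph_adjacency(graph)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(A[nb, nb]) / 2
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_components <- function(graph) {
  n <- graph$n_nodes
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(graph$edges))) {
    a <- find(graph$edges$i[e]); b <- find(graph$edges$j[e])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

oracle_eigenvector <- function(graph) {
  n <- graph$n_nodes
  A <- graph_adjacency(graph)
  # largest component by union-find-free scan over the reachability of FW
  D <- oracle_floyd_warshall(graph)
  labels <- integer(n); lab <- 0
  for (i in seq_len(n)) {
    if (labels[i] == 0) { lab <- lab + 1; labels[is.finite(D[i, ])] <- lab }
  }
  sizes <- tabulate(labels)
  big <- which(sizes == max(sizes))[1]
  idx <- which(labels == big)
  vals <- numeric(n)
  if (sum(A[idx, idx]) == 0) return(vals)
  ev <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- abs(v) / sqrt(sum(v^2))
  vals[idx] <- v
  vals
}

oracle_local_apl <- function(graph) {
  D <- oracle_floyd_warshall(graph)
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    gi <- D[i, -i]; gi <- gi[is.finite(gi)]
    if (!length(gi)) 0 else mean(gi)
  }, numeric(1))
}

# rigid-motion (rotation/reflection + translation) Procrustes residual
procrustes_rms <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  sqrt(mean((B %*% R - A)^2))
}

# fixture generators for the classifier tests ------------------------------

ring_fixture <- function(seed = 3, n = 30, r1 = 1, r2 = 1.25, noise = 0.02) {
  set.seed(seed)
  th1 <- 2 * pi * (0:(n - 1)) / n
  th2 <- 2 * pi * ((0:(n - 1)) + 0.5) / n
  X <- rbind(cbind(r1 * cos(th1), r1 * sin(th1)) + matrix(rnorm(2 * n, 0, noise), n, 2),
             cbind(r2 * cos(th2), r2 * sin(th2)) + matrix(rnorm(2 * n, 0, noise), n, 2))
  list(x = X, y = rep(c("inner", "outer"), each = n))
}

blob_fixture <- function(seed = 2, n = 10, d = 6, sep = 3, sd = 0.1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d, 0, sd), n, d),
             matrix(rnorm(n * d, sep, sd), n, d))
  list(x = X, y = rep(c("a", "b"), each = n))
}

loocv_linear_svm <- function(x, y) {
  pred <- vapply(seq_along(y), function(i) {
    f <- e1071::svm(x[-i, , drop = FALSE], factor(y[-i]),
                    kernel = "linear", scale = FALSE)
    as.character(stats::predict(f, x[i, , drop = FALSE]))
  }, character(1))
  mean(pred == y)
}
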