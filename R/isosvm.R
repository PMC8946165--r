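# IsoSVM: Isomap embedding of per-lesion graph-metric features followed by a
# support vector machine with per-class misclassification penalties, tuned by
# grid search under leave-one-out cross-validation. The Isomap step supplies
# the nonlinearity; the SVM on the embedded coordinates stays linear by
# default.

#' Assemble the per-lesion classification table
#'
#' @param features Numeric matrix, one row per lesion (typically
#'   [as_feature_vector()] outputs stacked with `rbind`).
#' @param labels Binary class per row (factor, character or logical).
#' @param ids Optional lesion identifiers.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, labels, ids = NULL) {
  x <- as.matrix(features)
  if (anyNA(x) || !all(is.finite(x))) {
    stop_tcf("feature table contains missing or non-finite values",
             class = "tcf_data_error")
  }
  y <- factor(labels)
  if (nlevels(y) != 2L) stop_tcf("exactly two classes required", class = "tcf_class_error")
  if (length(y) != nrow(x)) stop_tcf("labels/rows length mismatch", class = "tcf_spec_error")
  structure(list(x = x, y = y, ids = ids %||% seq_len(nrow(x))),
            class = "feature_table")
}

# Smallest k whose union k-NN graph over the rows is connected.
smallest_connecting_k <- function(d) {
  n <- nrow(d)
  for (k in seq_len(n - 1L)) {
    g <- build_graph(d, neighborhood_spec("knn", k = k))
    if (igraph::components(as_igraph(g))$no == 1L) return(k)
  }
  n - 1L
}

# Bridge a disconnected row graph: repeatedly join the two components whose
# closest cross pair is smallest (a minimum-spanning joining of components).
augment_connect <- function(graph, d) {
  g <- as_igraph(graph)
  memb <- igraph::components(g)$membership
  while (length(unique(memb)) > 1L) {
    best <- c(Inf, NA, NA)
    for (ci in unique(memb)) {
      a <- which(memb == ci); b <- which(memb != ci)
      sub <- d[a, b, drop = FALSE]
      m <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      if (sub[m[1], m[2]] < best[1]) best <- c(sub[m[1], m[2]], a[m[1]], b[m[2]])
    }
    i <- min(best[2], best[3]); j <- max(best[2], best[3])
    graph$edges <- rbind(graph$edges, data.frame(i = i, j = j, w = best[1]))
    memb[memb == memb[j]] <- memb[i]
  }
  graph$edges <- graph$edges[order(graph$edges$i, graph$edges$j), , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Isomap embedding of feature-space rows
#'
#' Classical multidimensional scaling of the geodesic distances along the
#' union k-NN graph over the rows: the squared-geodesic matrix is
#' double-centered and the top eigenvectors, scaled by the square root of
#' their eigenvalues, give the embedded coordinates. Each axis follows a
#' deterministic sign convention (its largest-magnitude coordinate is made
#' positive).
#'
#' @param x Numeric matrix of rows to embed (or a `feature_table`).
#' @param embed_k Neighborhood size of the row graph.
#' @param embed_dim Target dimension (must be below the number of rows).
#' @param connect What to do when the row graph is disconnected: `"error"`
#'   (default; the error names the smallest k that connects the rows) or
#'   `"augment"` (join components through their closest cross pairs, the
#'   behavior used inside [fit_isosvm()] so that well-separated classes do
#'   not abort the fit).
#' @return An `isomap_embedding`: list with `points` (n x embed_dim), plus
#'   the eigenvectors, eigenvalues, geodesic matrix and training rows needed
#'   for out-of-sample extension.
#' @export
isomap_embed <- function(x, embed_k, embed_dim, connect = c("error", "augment")) {
  connect <- match.arg(connect)
  if (inherits(x, "feature_table")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x)
  if (embed_dim >= n) stop_tcf("embed_dim must be < number of rows", class = "tcf_spec_error")
  d <- euclidean_matrix(x)
  graph <- build_graph(d, neighborhood_spec("knn", k = min(embed_k, n - 1L)))
  if (igraph::components(as_igraph(graph))$no > 1L) {
    if (connect == "error") {
      stop_tcf("row k-NN graph is disconnected at k = ", embed_k,
               "; smallest connecting k is ", smallest_connecting_k(d),
               class = "tcf_disconnected_error")
    }
    graph <- augment_connect(graph, unclass(d))
  }
  G <- geodesic_matrix(graph)$g
  D2 <- G^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  lam <- ev$values[seq_len(embed_dim)]
  V <- ev$vectors[, seq_len(embed_dim), drop = FALSE]
  lam[lam < 0] <- 0
  # sign convention: largest-magnitude entry of each axis positive
  for (a in seq_len(embed_dim)) {
    top <- which.max(abs(V[, a]))
    if (V[top, a] < 0) V[, a] <- -V[, a]
  }
  pts <- sweep(V, 2, sqrt(lam), `*`)
  structure(list(points = pts,
                 eigvecs = V, eigvals = lam,
                 geodesics = G, row_mean_sq = rowMeans(D2),
                 x = x, embed_k = embed_k, embed_dim = embed_dim,
                 connect = connect),
            class = "isomap_embedding")
}

#' Place new rows into an existing Isomap embedding
#'
#' Nystrom-style interpolation: the new row's geodesic distance to each
#' training row is approximated through its `embed_k` nearest training rows
#' (`min over m of d(new, m) + G(m, j)`), and the classical-MDS projection
#' formula maps the squared geodesics onto the stored axes. A training row
#' re-embedded this way reproduces its training coordinates.
#'
#' @param embedding An [isomap_embed()] result.
#' @param newx Matrix of new rows (same feature dimension).
#' @return Matrix of embedded coordinates (possibly 0 rows).
#' @export
embed_out_of_sample <- function(embedding, newx) {
  newx <- as.matrix(newx)
  if (nrow(newx) == 0L) {
    return(matrix(numeric(0), 0, embedding$embed_dim))
  }
  if (ncol(newx) != ncol(embedding$x)) {
    stop_tcf("new rows have ", ncol(newx), " features; embedding expects ",
             ncol(embedding$x), class = "tcf_schema_error")
  }
  n <- nrow(embedding$x)
  k <- min(embedding$embed_k, n)
  lam <- embedding$eigvals
  scale <- ifelse(lam > 0, 1 / (2 * sqrt(lam)), 0)
  out <- matrix(0, nrow(newx), embedding$embed_dim)
  for (r in seq_len(nrow(newx))) {
    dn <- sqrt(colSums((t(embedding$x) - newx[r, ])^2))
    nb <- order(dn, seq_len(n))[seq_len(k)]
    gnew <- apply(dn[nb] + embedding$geodesics[nb, , drop = FALSE], 2, min)
    delta <- gnew^2
    out[r, ] <- as.vector(crossprod(embedding$eigvecs,
                                    embedding$row_mean_sq - delta)) * scale
  }
  out
}

# Per-class SVM cost weights: inverse class frequency (n / (2 n_class)),
# or equal weighting.
class_penalties <- function(y, mode = c("inverse_frequency", "equal")) {
  mode <- match.arg(mode)
  tab <- table(y)
  if (mode == "equal") {
    w <- stats::setNames(rep(1, length(tab)), names(tab))
  } else {
    w <- length(y) / (2 * as.numeric(tab))
    names(w) <- names(tab)
  }
  w
}

# Decision scores oriented so larger = positive class (second factor level).
oriented_decision <- function(svmfit, newdata, positive) {
  pr <- stats::predict(svmfit, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lv <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  score <- if (lv[1] == positive) dv[, 1] else -dv[, 1]
  list(labels = pr, score = as.numeric(score))
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1  # constant features pass through centered
  list(center = mu, scale = sd)
}

standardize_apply <- function(x, s) {
  sweep(sweep(x, 2, s$center), 2, s$scale, `/`)
}

#' Fit the IsoSVM classifier with grid search under leave-one-out CV
#'
#' For every grid point the data are standardized on the n-1 training rows of
#' each fold, Isomap-embedded (components bridged when disconnected), the
#' held-out row is placed by out-of-sample extension, and a linear SVM with
#' per-class penalties predicts it. The grid point maximizing LOOCV balanced
#' accuracy wins (ties: smaller `embed_dim`, then smaller `C`, then smaller
#' `embed_k`); the model is then refit on all rows.
#'
#' @param table A [feature_table()] with at least 2 rows per class.
#' @param grid Data frame with columns `embed_k`, `embed_dim`, `C`; default
#'   `embed_k` in \{4, 6, 8\}, `embed_dim` in \{2, 3, 4\}, `C` in
#'   \{0.1, 1, 10\}.
#' @param weights `"inverse_frequency"` (default) or `"equal"` per-class
#'   penalties.
#' @param criterion `"balanced_accuracy"` (default) or `"accuracy"` for grid
#'   selection.
#' @param seed Seed (the fit itself is deterministic; recorded for
#'   provenance).
#' @return List with `model` (an `isosvm_model`) and `cv` (per-row held-out
#'   predictions and scores for the chosen grid point, the full grid table,
#'   and LOOCV accuracy / sensitivity / specificity).
#' @export
fit_isosvm <- function(table, grid = default_isosvm_grid(),
                       weights = c("inverse_frequency", "equal"),
                       criterion = c("balanced_accuracy", "accuracy"),
                       seed = NULL) {
  weights <- match.arg(weights)
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "feature_table"))
  if (any(table(table$y) < 2L)) {
    stop_tcf("need at least 2 rows per class", class = "tcf_class_error")
  }
  if (is.null(grid) || nrow(grid) == 0L) stop_tcf("empty grid", class = "tcf_spec_error")
  x <- table$x; y <- table$y; n <- nrow(x)
  positive <- levels(y)[2]
  grid <- grid[grid$embed_dim < n - 1L, , drop = FALSE]
  if (nrow(grid) == 0L) stop_tcf("no feasible grid point (embed_dim too large)",
                                 class = "tcf_spec_error")
  # held-out prediction store: rows = grid points, cols = folds
  pred <- matrix(NA_character_, nrow(grid), n)
  score <- matrix(NA_real_, nrow(grid), n)
  ks <- sort(unique(grid$embed_k))
  for (fold in seq_len(n)) {
    xtr <- x[-fold, , drop = FALSE]; ytr <- y[-fold]
    if (nlevels(droplevels(ytr)) < 2L) next
    std <- standardize_fit(xtr)
    xs <- standardize_apply(xtr, std)
    xh <- standardize_apply(x[fold, , drop = FALSE], std)
    for (k in ks) {
      rows_k <- which(grid$embed_k == k)
      dmax <- max(grid$embed_dim[rows_k])
      emb <- isomap_embed(xs, embed_k = k, embed_dim = min(dmax, n - 2L),
                          connect = "augment")
      yh_all <- embed_out_of_sample(emb, xh)
      for (gi in rows_k) {
        dm <- grid$embed_dim[gi]
        ytrain <- emb$points[, seq_len(dm), drop = FALSE]
        yheld <- yh_all[, seq_len(dm), drop = FALSE]
        fit <- e1071::svm(ytrain, ytr, kernel = "linear", cost = grid$C[gi],
                          class.weights = class_penalties(ytr, weights),
                          scale = FALSE)
        od <- oriented_decision(fit, yheld, positive)
        pred[gi, fold] <- as.character(od$labels)
        score[gi, fold] <- od$score
      }
    }
  }
  crit <- vapply(seq_len(nrow(grid)), function(gi) {
    ph <- factor(pred[gi, ], levels = levels(y))
    ok <- !is.na(ph)
    if (!any(ok)) return(-Inf)
    if (criterion == "accuracy") return(mean(ph[ok] == y[ok]))
    rec <- vapply(levels(y), function(l) {
      m <- ok & y == l
      if (!any(m)) return(NA_real_)
      mean(ph[m] == l)
    }, numeric(1))
    mean(rec, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-crit, grid$embed_dim, grid$C, grid$embed_k)
  best <- ord[1]
  # refit on all rows
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  emb <- isomap_embed(xs, embed_k = grid$embed_k[best],
                      embed_dim = grid$embed_dim[best], connect = "augment")
  fit <- e1071::svm(emb$points, y, kernel = "linear", cost = grid$C[best],
                    class.weights = class_penalties(y, weights), scale = FALSE)
  model <- structure(list(svm = fit, embedding = emb, standardize = std,
                          embed_k = grid$embed_k[best],
                          embed_dim = grid$embed_dim[best],
                          C = grid$C[best],
                          class_penalties = class_penalties(y, weights),
                          weights = weights, levels = levels(y),
                          positive = positive,
                          feature_names = colnames(x), seed = seed),
                     class = "isosvm_model")
  yhat <- factor(pred[best, ], levels = levels(y))
  cm <- table(truth = y, pred = yhat)
  cv <- list(grid = cbind(grid, criterion = crit),
             chosen = grid[best, , drop = FALSE],
             predictions = yhat,
             scores = score[best, ],
             truth = y,
             accuracy = mean(yhat == y, na.rm = TRUE),
             sensitivity = sens_spec(yhat, y, positive = positive)[["sensitivity"]],
             specificity = sens_spec(yhat, y, positive = positive)[["specificity"]])
  list(model = model, cv = cv)
}

#' Default IsoSVM hyperparameter grid
#' @export
default_isosvm_grid <- function() {
  expand.grid(embed_k = c(4L, 6L, 8L), embed_dim = c(2L, 3L, 4L),
              C = c(0.1, 1, 10), KEEP.OUT.ATTRS = FALSE)
}

#' @export
print.isosvm_model <- function(x, ...) {
  cat("<isosvm_model> embed_k =", x$embed_k, "| embed_dim =", x$embed_dim,
      "| C =", x$C, "| classes:", paste(x$levels, collapse = " vs "), "\n")
  invisible(x)
}

#' Predict classes and decision scores for new lesions
#'
#' New rows are standardized with the stored parameters, placed into the
#' training embedding by out-of-sample extension, and scored by the SVM.
#' Decision scores are oriented so that larger values favor the positive
#' (second) class; they are the continuous inputs to ROC / precision-recall
#' analysis.
#'
#' @param object An `isosvm_model`.
#' @param newdata Matrix of feature rows (columns matching the training
#'   features) or a `feature_table`.
#' @param ... Unused.
#' @return List with `labels` (factor) and `score` (numeric).
#' @export
predict.isosvm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(list(labels = factor(character(0), levels = object$levels),
                score = numeric(0)))
  }
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop_tcf("feature names do not match the training features",
             class = "tcf_schema_error")
  }
  xs <- standardize_apply(newdata, object$standardize)
  emb <- embed_out_of_sample(object$embedding, xs)
  od <- oriented_decision(object$svm, emb, object$positive)
  list(labels = factor(as.character(od$labels), levels = object$levels),
       score = od$score)
}
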