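# End-to-end orchestration: simulate -> build -> metrics -> classify ->
# evaluate -> visualize, driven by one serializable config, with a checksum
# manifest so reruns are verifiably identical.

#' Extract a 2D slice from an image or mask
#'
#' @param x A [mp_image()] or [roi_mask()] with a 3D grid.
#' @param axis Slicing axis.
#' @param index Slice index (1-based).
#' @return The 2D object.
#' @export
take_slice <- function(x, axis, index) {
  pick <- function(arr) {
    out <- switch(as.integer(axis),
                  `1` = arr[index, , ], `2` = arr[, index, ], `3` = arr[, , index])
    out
  }
  if (inherits(x, "mp_image")) {
    chans <- lapply(x$channels, pick)
    img <- mp_image(chans, spacing = x$spacing[setdiff(1:3, axis)])
    img$normalized <- x$normalized
    img
  } else if (inherits(x, "roi_mask")) {
    roi_mask(pick(x$voxels), label = x$label)
  } else {
    stop_tcf("unsupported object", class = "tcf_spec_error")
  }
}

#' Build the full connectome of one lesion
#'
#' Convenience chain: optional largest-diameter slice selection (3D inputs),
#' normalization (when not already normalized), signature extraction,
#' distance matrix, neighborhood graph, geodesics, node maps and the global
#' summary.
#'
#' @param image A [mp_image()].
#' @param mask A [roi_mask()] on the same grid.
#' @param spec A [neighborhood_spec()].
#' @param cap,seed Subsampling cap and seed for [extract_signatures()].
#' @param slice_axis For 3D inputs, the axis along which the analysis slice
#'   (largest in-plane lesion extent) is picked; `NULL` keeps the full grid.
#' @return List with `signatures`, `graph`, `geodesics`, `summary`, `maps`
#'   (named list of the six `node_metric_map`s) and, for 3D inputs,
#'   `slice_index`.
#' @export
lesion_connectome <- function(image, mask, spec = neighborhood_spec(),
                              cap = 2000L, seed = NULL, slice_axis = NULL) {
  slice_index <- NULL
  if (!is.null(slice_axis) && length(image$shape) == 3L) {
    slice_index <- select_largest_slice(mask, axis = slice_axis)
    image <- take_slice(image, slice_axis, slice_index)
    mask <- take_slice(mask, slice_axis, slice_index)
  }
  if (!all(image$normalized)) image <- normalize_channels(image)
  sig <- extract_signatures(image, mask, subsample_cap = cap, seed = seed)
  d <- euclidean_matrix(sig)
  graph <- build_graph(d, spec, node_coords = sig$coords)
  geo <- geodesic_matrix(graph)
  maps <- list(degree_centrality = degree_centrality(graph),
               betweenness_centrality = betweenness_centrality(graph),
               eigenvector_centrality = eigenvector_centrality(graph),
               clustering_coefficient = clustering_coefficient(graph),
               average_path_length = local_average_path_length(geo, sig$coords),
               node_strength = node_strength(graph))
  summ <- summarize_connectome(graph, geo,
                               provenance = c(sig$provenance,
                                              list(slice_index = slice_index)))
  list(signatures = sig, graph = graph, geodesics = geo,
       summary = summ, maps = maps, slice_index = slice_index)
}

#' Connectome summaries for a whole cohort
#'
#' @param cohort A [generate_cohort()] result, or any list of subjects with
#'   `image`, `mask`, `label`, `id` elements.
#' @param spec,cap,seed Passed to [lesion_connectome()] (each subject gets a
#'   derived sub-seed).
#' @param keep Return the full per-subject connectome objects as well.
#' @return List with `summaries` (data frame, one row per subject),
#'   `features` (matrix of the six metric means plus `n_components`),
#'   `labels`, and optionally `connectomes`.
#' @export
cohort_connectomes <- function(cohort, spec = neighborhood_spec(),
                               cap = 2000L, seed = 1L, keep = FALSE) {
  rows <- list(); feats <- list(); conns <- list()
  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    cx <- tryCatch(
      lesion_connectome(subj$image, subj$mask, spec = spec, cap = cap,
                        seed = derive_seed(seed, s)),
      error = function(e) {
        stop_tcf("subject '", subj$id %||% s, "': ", conditionMessage(e),
                 class = "tcf_stage_error")
      })
    fv <- as_feature_vector(cx$summary)
    rows[[s]] <- data.frame(id = subj$id %||% as.character(s),
                            label = subj$label %||% NA_character_,
                            n_nodes = cx$summary$n_nodes,
                            t(fv))
    feats[[s]] <- fv
    if (keep) conns[[s]] <- cx
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  out <- list(summaries = summaries,
              features = do.call(rbind, feats),
              labels = vapply(cohort, function(s) s$label %||% NA_character_, ""))
  if (keep) out$connectomes <- conns
  out
}

#' Assemble and validate a pipeline configuration
#'
#' All stage parameters in one serializable list; every value has a logged
#' default so a completed run documents the exact settings used.
#'
#' @param seed Master seed for the run.
#' @param n_per_class Simulated subjects per class.
#' @param mode,k,t Neighborhood rule (see [neighborhood_spec()]).
#' @param cap Signature subsampling cap.
#' @param n_boot Bootstrap resamples for the evaluation report.
#' @param render Write overlay figures.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 13L, n_per_class = 10L, mode = "knn", k = 5L,
                       t = NULL, cap = 2000L, n_boot = 500L, render = TRUE) {
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 mode = mode, k = k, t = t, cap = as.integer(cap),
                 n_boot = as.integer(n_boot), render = isTRUE(render),
                 version = as.character(utils::packageVersion("tumorconnectome"))),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_tcf("config not found: ", path, class = "tcf_config_error")
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Run the simulate-to-evaluate pipeline
#'
#' Simulates a two-class phantom cohort, builds every connectome, writes the
#' per-lesion summaries and metric-by-metric group comparison, fits IsoSVM
#' under LOOCV, evaluates its held-out decision scores, renders one overlay
#' per class, and writes a manifest with an MD5 checksum per artifact.
#' Rerunning with the same config reproduces every checksum.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; the manifest is at `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- neighborhood_spec(config$mode, k = config$k %||% 5L, t = config$t)
  cohort <- generate_cohort(config$n_per_class, seed = config$seed)
  cc <- cohort_connectomes(cohort, spec = spec, cap = config$cap,
                           seed = derive_seed(config$seed, 2), keep = TRUE)
  write_csv_num <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    file
  }
  files <- character(0)
  files <- c(files, write_csv_num(cc$summaries, "summaries.csv"))
  cmp <- compare_groups(cc$features, cc$labels, positive = "malignant")
  files <- c(files, write_csv_num(cmp, "group_comparison.csv"))
  ft <- feature_table(cc$features, cc$labels,
                      ids = cc$summaries$id)
  fit <- fit_isosvm(ft, seed = derive_seed(config$seed, 3))
  cvdf <- data.frame(id = cc$summaries$id, truth = as.character(fit$cv$truth),
                     prediction = as.character(fit$cv$predictions),
                     score = fit$cv$scores)
  files <- c(files, write_csv_num(cvdf, "isosvm_cv.csv"))
  jsonlite::write_json(
    list(embed_k = fit$model$embed_k, embed_dim = fit$model$embed_dim,
         C = fit$model$C, weights = fit$model$weights,
         class_penalties = as.list(fit$model$class_penalties),
         loocv_accuracy = fit$cv$accuracy, config = unclass(config)),
    file.path(out_dir, "isosvm_model.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "isosvm_model.json")
  rep <- eval_report(fit$cv$scores, fit$cv$truth, n_boot = config$n_boot,
                     seed = derive_seed(config$seed, 4))
  jsonlite::write_json(unclass(rep), file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "eval_report.json")
  if (config$render) {
    for (cls in c("benign", "malignant")) {
      i <- which(cc$labels == cls)[1]
      cx <- cc$connectomes[[i]]
      ospec <- overlay_spec("ch1", "degree_centrality")
      f <- paste0("overlay_", cls, ".png")
      render_overlay(cohort[[i]]$image, cx$graph, cx$maps$degree_centrality,
                     ospec, file.path(out_dir, f),
                     svg = file.path(out_dir, paste0("overlay_", cls, ".svg")))
      files <- c(files, f, paste0("overlay_", cls, ".svg"))
    }
  }
  sums <- tools::md5sum(file.path(out_dir, sort(files)))
  manifest <- list(config = unclass(config),
                   artifacts = stats::setNames(as.list(unname(sums)), sort(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
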