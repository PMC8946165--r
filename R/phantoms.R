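# Seeded multiparametric phantom lesions. A phantom is a multi-channel 2D
# slice with a disk-shaped lesion whose voxel intensities follow per-cluster
# channel means plus Gaussian noise: one intensity cluster gives a
# homogeneous "benign-like" lesion, several spatially Voronoi-partitioned
# clusters give a heterogeneous "malignant-like" mosaic. Same seed, same
# phantom, bit for bit.

#' Phantom lesion specification
#'
#' @param grid Integer grid size (2D slice), default 64 x 64.
#' @param n_channels Number of imaging channels (default 3, e.g. T1post / T2 /
#'   ADC-like).
#' @param center Lesion center (defaults to the grid center).
#' @param radius Lesion disk radius in voxels.
#' @param n_clusters Number of intensity clusters: 1 = homogeneous
#'   benign-like, 3+ = malignant-like mosaic.
#' @param cluster_means `n_clusters` x `n_channels` matrix of per-cluster
#'   channel means in \[0, 1\]; defaults to a chain layout with adjacent means
#'   3.2 noise-SDs apart (see [make_cluster_means()]).
#' @param noise_sd Gaussian noise SD added per voxel and channel
#'   (default 0.05).
#' @param noise_cor Correlation of the noise across channels (default 0).
#'   Homogeneous tissue tends to vary along one latent factor (density /
#'   partial volume) that moves all sequences together, which a high
#'   correlation emulates; heterogeneous tissue mixes independent processes.
#' @param background Background channel mean outside the lesion
#'   (default 0.12).
#' @param seed RNG seed.
#' @param check_separation Enforce that all cluster means are at least 3
#'   noise-SDs apart (default; disabled internally for homogenized follow-up
#'   phantoms, where merging clusters is the point).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64L, 64L), n_channels = 3L, center = NULL,
                         radius = 7L, n_clusters = 1L, cluster_means = NULL,
                         noise_sd = 0.05, noise_cor = 0, background = 0.12,
                         seed = 1L, check_separation = TRUE) {
  grid <- as.integer(grid)
  center <- center %||% ceiling(grid / 2)
  if (is.null(cluster_means)) {
    cluster_means <- make_cluster_means(n_clusters, n_channels,
                                        step = 3.2 * noise_sd)
  }
  cluster_means <- matrix(cluster_means, nrow = n_clusters, ncol = n_channels)
  if (any(center - radius < 1) || any(center + radius > grid)) {
    stop_tcf("lesion (center ", paste(center, collapse = ","), ", radius ",
             radius, ") does not fit the grid", class = "tcf_spec_error")
  }
  if (check_separation && n_clusters > 1L) {
    sep <- min(stats::dist(cluster_means))
    if (sep < 3 * noise_sd) {
      stop_tcf("cluster means separated by ", signif(sep, 3),
               " < 3 x noise SD (", 3 * noise_sd, ")", class = "tcf_spec_error")
    }
  }
  structure(list(grid = grid, n_channels = as.integer(n_channels),
                 center = as.integer(center), radius = as.integer(radius),
                 n_clusters = as.integer(n_clusters),
                 cluster_means = cluster_means, noise_sd = noise_sd,
                 noise_cor = noise_cor, background = background,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Hierarchical layout of cluster channel means
#'
#' Clusters are laid out in pairs of "habitats": habitat centers sit
#' `split_step` apart (default 8 noise-SDs, far enough that the voxel graph
#' reliably splits into separate components), and the two clusters within a
#' habitat sit `step` apart (default 3.2 noise-SDs, close enough that their
#' intensity tails overlap and the graph bridges them through a sparse,
#' path-lengthening neck). This mirrors the two signatures of a
#' heterogeneous lesion: disjoint microenvironments plus graded transitions
#' within them.
#'
#' @param n_clusters,n_channels Layout dimensions.
#' @param base Base mean per channel (default 0.3).
#' @param step Within-habitat distance between cluster means.
#' @param split_step Between-habitat distance.
#' @return `n_clusters` x `n_channels` matrix.
#' @export
make_cluster_means <- function(n_clusters, n_channels, base = 0.3,
                               step = 0.16, split_step = 0.4) {
  m <- matrix(base, n_clusters, n_channels)
  if (n_clusters > 1L) {
    for (c in 2:n_clusters) {
      hab <- (c - 1L) %/% 2L          # habitat index, 0-based
      m[c, ] <- base
      if (hab > 0L) {                 # habitat centers fan out over the axes
        ax_split <- (hab - 1L) %% n_channels + 1L
        m[c, ax_split] <- m[c, ax_split] + split_step * (1 + (hab - 1L) %/% n_channels)
      }
      if ((c - 1L) %% 2L == 1L) {     # second member of its habitat
        ax_step <- n_channels         # last axis stays free of habitat splits
        m[c, ax_step] <- m[c, ax_step] + step
      }
    }
  }
  pmin(pmax(m, 0), 1)
}

#' Convenience specs for the two phantom classes
#'
#' Benign-like: small (radius 7) homogeneous single-cluster lesion whose
#' channel noise is strongly correlated (`noise_cor = 0.85`): one tissue
#' type whose sequences move together, giving a compact, well-knit network.
#' Malignant-like: larger (radius 11) four-cluster mosaic (two habitat pairs,
#' see [make_cluster_means()]) with weakly correlated channels
#' (`noise_cor = 0.3`). Both on a 64 x 64 three-channel slice with noise SD
#' 0.05.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [phantom_spec()].
#' @name class_specs
#' @export
benign_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(radius = 7L, n_clusters = 1L,
                                 cluster_means = matrix(0.45, 1, 3),
                                 noise_cor = 0.85, seed = seed),
                            list(...))
  do.call(phantom_spec, args)
}

#' @rdname class_specs
#' @export
malignant_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(radius = 11L, n_clusters = 4L,
                                 noise_cor = 0.3, seed = seed),
                            list(...))
  do.call(phantom_spec, args)
}

#' Generate one phantom lesion
#'
#' Channels are per-voxel cluster mean plus Gaussian noise, clipped to
#' \[0, 1\]; the mask is the lesion disk. For 2 or more clusters, voxels are
#' assigned to clusters by a seeded spatial Voronoi partition of the lesion
#' (cluster sites drawn uniformly from the lesion disk), emulating spatially
#' coherent tissue habitats without imposing radial structure.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [mp_image()], flagged normalized since all
#'   intensities are unit-scaled by construction), `mask` (a [roi_mask()])
#'   and `cluster_of` (per-lesion-voxel cluster index).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  rows <- matrix(seq_len(g[1]), g[1], g[2])
  cols <- matrix(seq_len(g[2]), g[1], g[2], byrow = TRUE)
  inside <- (rows - spec$center[1])^2 + (cols - spec$center[2])^2 <= spec$radius^2
  lesion_idx <- which(inside)
  with_seed(spec$seed, {
    if (spec$n_clusters >= 2L) {
      sites <- sample(lesion_idx, spec$n_clusters)
      sr <- arrayInd(sites, g)
      lr <- arrayInd(lesion_idx, g)
      d2 <- outer(lr[, 1], sr[, 1], `-`)^2 + outer(lr[, 2], sr[, 2], `-`)^2
      cluster_of <- max.col(-d2, ties.method = "first")
    } else {
      cluster_of <- rep(1L, length(lesion_idx))
    }
    chans <- vector("list", spec$n_channels)
    rho <- spec$noise_cor
    shared <- matrix(stats::rnorm(prod(g)), g[1], g[2])  # cross-channel factor
    for (ch in seq_len(spec$n_channels)) {
      v <- matrix(spec$background, g[1], g[2])
      v[lesion_idx] <- spec$cluster_means[cluster_of, ch]
      z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(prod(g)), g[1], g[2])
      chans[[ch]] <- pmin(pmax(v + spec$noise_sd * z, 0), 1)
    }
    names(chans) <- paste0("ch", seq_len(spec$n_channels))
    img <- mp_image(chans)
    img$normalized[] <- TRUE  # unit-scaled by construction
    list(image = img,
         mask = roi_mask(inside, label = "lesion"),
         cluster_of = cluster_of)
  })
}

#' Generate a labeled two-class phantom cohort
#'
#' Each subject gets a derived sub-seed, a shared per-subject shift of the
#' cluster means (SD 0.02 per channel, applied to all clusters alike so the
#' between-cluster separations are preserved) and a radius jitter of at most
#' one voxel, so subjects differ while the class contrast stays fixed.
#'
#' @param n_per_class Subjects per class (at least 2).
#' @param benign_spec,malignant_spec Template [phantom_spec()]s for the two
#'   classes.
#' @param seed Cohort seed.
#' @return List of subjects, each a list with `image`, `mask`, `label`
#'   (`"benign"`/`"malignant"`), `id` and `seed`.
#' @export
generate_cohort <- function(n_per_class, benign_spec = benign_phantom_spec(),
                            malignant_spec = malignant_phantom_spec(),
                            seed = 1L) {
  if (n_per_class < 2L) stop_tcf("n_per_class must be >= 2", class = "tcf_spec_error")
  subjects <- list()
  templates <- list(benign = benign_spec, malignant = malignant_spec)
  for (cls in names(templates)) {
    for (s in seq_len(n_per_class)) {
      sub_seed <- derive_seed(seed, 1000 * match(cls, names(templates)) + s)
      tpl <- templates[[cls]]
      jit <- with_seed(sub_seed, list(
        shift = stats::rnorm(tpl$n_channels, sd = 0.02),
        dr = sample(-1:1, 1)))
      sp <- phantom_spec(grid = tpl$grid, n_channels = tpl$n_channels,
                         center = tpl$center,
                         radius = max(tpl$radius + jit$dr, 3L),
                         n_clusters = tpl$n_clusters,
                         cluster_means = pmin(pmax(
                           sweep(tpl$cluster_means, 2, jit$shift, `+`), 0), 1),
                         noise_sd = tpl$noise_sd, noise_cor = tpl$noise_cor,
                         background = tpl$background,
                         seed = derive_seed(sub_seed, 7))
      ph <- generate_phantom(sp)
      subjects[[length(subjects) + 1L]] <-
        list(image = ph$image, mask = ph$mask, label = cls,
             id = sprintf("%s_%02d", cls, s), seed = sub_seed)
    }
  }
  subjects
}

#' Generate a baseline / follow-up phantom pair
#'
#' Responders shrink (radius scaled by 0.6) and homogenize (cluster means
#' pulled toward their centroid by a contrast factor of 0.3); non-responders
#' keep their radius and cluster contrast. Voxel noise is redrawn at
#' follow-up, as a fresh scan would be.
#'
#' @param spec Baseline [phantom_spec()] (typically malignant-like).
#' @param responder Logical.
#' @param radius_factor,contrast_factor Override the follow-up transform.
#' @return List with `baseline` and `followup`, each as returned by
#'   [generate_phantom()].
#' @export
generate_longitudinal_pair <- function(spec, responder,
                                       radius_factor = NULL,
                                       contrast_factor = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  radius_factor <- radius_factor %||% if (responder) 0.6 else 1.0
  contrast_factor <- contrast_factor %||% if (responder) 0.3 else 1.0
  baseline <- generate_phantom(spec)
  centroid <- colMeans(spec$cluster_means)
  means_f <- sweep(sweep(spec$cluster_means, 2, centroid, `-`) * contrast_factor,
                   2, centroid, `+`)
  spec_f <- phantom_spec(grid = spec$grid, n_channels = spec$n_channels,
                         center = spec$center,
                         radius = max(as.integer(round(spec$radius * radius_factor)), 3L),
                         n_clusters = spec$n_clusters, cluster_means = means_f,
                         noise_sd = spec$noise_sd, noise_cor = spec$noise_cor,
                         background = spec$background,
                         seed = derive_seed(spec$seed, 101),
                         check_separation = contrast_factor >= 1)
  list(baseline = baseline, followup = generate_phantom(spec_f))
}
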