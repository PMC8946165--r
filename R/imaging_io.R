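#' Read a scalar image volume as a named channel
#'
#' Reads a NIfTI volume (`.nii` / `.nii.gz`) and tags it with a channel name
#' so it can be assembled into a [mp_image()]. Voxel order follows the file's
#' affine, which is kept as an attribute for provenance.
#'
#' @param path Path to a NIfTI file.
#' @param channel_name Name of the imaging channel (e.g. `"T1post"`, `"ADC"`).
#' @param volume For 4D files, the index along the fourth axis to extract.
#'   Reading a 4D file without `volume` is an error: the channel axis must
#'   be stated explicitly.
#' @return A numeric array of class `tcf_channel` with attributes
#'   `channel_name`, `spacing` (mm per axis) and `affine`.
#' @export
load_volume <- function(path, channel_name, volume = NULL) {
  if (!file.exists(path)) {
    stop_tcf("file not found: ", path, class = "tcf_format_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop_tcf("unreadable image '", path, "': ",
                             conditionMessage(e), class = "tcf_format_error")
                  })
  arr <- as.array(img)
  pix <- RNifti::pixdim(img)
  aff <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (length(dim(arr)) == 4L) {
    if (is.null(volume)) {
      stop_tcf("4D input '", path, "' needs an explicit `volume` index",
               class = "tcf_ambiguity_error")
    }
    arr <- arr[, , , volume, drop = TRUE]
    pix <- pix[seq_len(3)]
  }
  # collapse trailing singleton axes so single-slice files come back 2D
  d <- dim(arr)
  while (length(d) > 2L && d[length(d)] == 1L) {
    d <- d[-length(d)]
  }
  arr <- array(as.double(arr), dim = d)
  new_channel(arr, channel_name,
              spacing = as.double(pix[seq_along(d)]), affine = aff)
}

new_channel <- function(data, name, spacing = NULL, affine = NULL) {
  data <- array(as.double(data), dim = dim(data) %||% length(data))
  structure(data,
            channel_name = as.character(name),
            spacing = spacing %||% rep(1, length(dim(data))),
            affine = affine,
            class = "tcf_channel")
}

#' Assemble co-registered channels into a multiparametric image
#'
#' All channels must already live on one voxel grid; no resampling or
#' registration is attempted and a shape mismatch is a hard error.
#'
#' @param ... Channels from [load_volume()], or named numeric arrays.
#' @param spacing Optional voxel spacing (mm per axis); taken from the first
#'   channel when absent.
#' @return An object of class `mp_image`: a list with elements `channels`
#'   (named list of arrays), `shape`, `spacing` and `normalized` (per-channel
#'   logical).
#' @export
mp_image <- function(..., spacing = NULL) {
  chans <- list(...)
  if (length(chans) == 1L && is.list(chans[[1]]) && !inherits(chans[[1]], "tcf_channel")) {
    chans <- chans[[1]]
  }
  nm <- names(chans) %||% rep("", length(chans))
  for (i in seq_along(chans)) {
    if (inherits(chans[[i]], "tcf_channel") && !nzchar(nm[i])) {
      nm[i] <- attr(chans[[i]], "channel_name")
    }
  }
  if (length(chans) == 0L) stop_tcf("at least one channel required", class = "tcf_spec_error")
  if (any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop_tcf("channel names must be present and unique", class = "tcf_spec_error")
  }
  shape <- dim(chans[[1]]) %||% length(chans[[1]])
  for (i in seq_along(chans)) {
    di <- dim(chans[[i]]) %||% length(chans[[i]])
    if (!identical(as.integer(di), as.integer(shape))) {
      stop_tcf("channel '", nm[i], "' shape (", paste(di, collapse = "x"),
               ") does not match (", paste(shape, collapse = "x"), ")",
               class = "tcf_shape_error")
    }
  }
  if (is.null(spacing)) {
    spacing <- attr(chans[[1]], "spacing") %||% rep(1, length(shape))
  }
  chans <- lapply(chans, function(ch) array(as.double(ch), dim = shape))
  names(chans) <- nm
  structure(list(channels = chans,
                 shape = as.integer(shape),
                 spacing = as.double(spacing),
                 normalized = stats::setNames(rep(FALSE, length(chans)), nm)),
            class = "mp_image")
}

#' @export
print.mp_image <- function(x, ...) {
  cat("<mp_image> ", paste(x$shape, collapse = "x"),
      " | channels: ", paste(names(x$channels), collapse = ", "),
      " | normalized: ", all(x$normalized), "\n", sep = "")
  invisible(x)
}

#' Min-max normalize every channel to [0, 1]
#'
#' Each channel is mapped affinely to the unit interval in double precision:
#' `v' = (v - min) / (max - min)`. By default the extrema are taken over the
#' whole image; `within_mask` restricts them to a region of interest instead
#' (values outside the observed range are then clipped to \[0, 1\]).
#'
#' @param img A [mp_image()].
#' @param within_mask Optional [roi_mask()]: compute extrema over this region
#'   only.
#' @return The image with all channels normalized and flagged as such.
#' @export
normalize_channels <- function(img, within_mask = NULL) {
  stopifnot(inherits(img, "mp_image"))
  sel <- NULL
  if (!is.null(within_mask)) {
    check_same_grid(img, within_mask)
    sel <- which(within_mask$voxels)
  }
  for (nm in names(img$channels)) {
    v <- img$channels[[nm]]
    if (!all(is.finite(v))) {
      stop_tcf("channel '", nm, "' contains non-finite values", class = "tcf_data_error")
    }
    ref <- if (is.null(sel)) v else v[sel]
    lo <- min(ref); hi <- max(ref)
    if (hi == lo) {
      stop_tcf("channel '", nm, "' is constant (max == min); cannot normalize",
               class = "tcf_degenerate_channel_error")
    }
    out <- (v - lo) / (hi - lo)
    if (!is.null(sel)) out <- pmin(pmax(out, 0), 1)
    img$channels[[nm]] <- out
    img$normalized[[nm]] <- TRUE
  }
  img
}

#' Build a binary region-of-interest mask
#'
#' @param voxels Logical or numeric array on the image grid; any value `> 0`
#'   is inside the region.
#' @param label Role of the region: `"lesion"`, `"normal"` or `"peritumoral"`.
#' @return An object of class `roi_mask` with elements `voxels` (logical
#'   array), `label` and `count`.
#' @export
roi_mask <- function(voxels, label = c("lesion", "normal", "peritumoral")) {
  label <- match.arg(label)
  d <- dim(voxels) %||% length(voxels)
  vox <- array(as.logical(voxels > 0), dim = d)
  structure(list(voxels = vox, label = label, count = sum(vox)),
            class = "roi_mask")
}

#' Read a NIfTI mask
#'
#' @inheritParams load_volume
#' @param label Region role, as in [roi_mask()].
#' @export
load_mask <- function(path, label = "lesion") {
  ch <- load_volume(path, channel_name = "mask")
  m <- roi_mask(ch, label = label)
  attr(m, "spacing") <- attr(ch, "spacing")
  m
}

check_same_grid <- function(img, mask) {
  if (!identical(as.integer(dim(mask$voxels)), img$shape)) {
    stop_tcf("mask grid (", paste(dim(mask$voxels), collapse = "x"),
             ") does not match image grid (", paste(img$shape, collapse = "x"), ")",
             class = "tcf_shape_error")
  }
  invisible(TRUE)
}

#' Pick the analysis slice with the largest in-plane lesion extent
#'
#' Returns the index (1-based) of the slice along `axis` that maximizes the
#' maximum pairwise in-plane distance between mask voxels (a Feret-style
#' diameter). Ties are broken toward the lower slice index.
#'
#' @param mask A 3D [roi_mask()].
#' @param axis Axis along which slices are taken (default 3, axial).
#' @param spacing Optional length-3 voxel spacing used to measure in-plane
#'   distances in millimetres; voxel units when absent.
#' @return Integer slice index.
#' @export
select_largest_slice <- function(mask, axis = 3L, spacing = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  d <- dim(mask$voxels)
  if (length(d) != 3L) stop_tcf("slice selection needs a 3D mask", class = "tcf_spec_error")
  if (mask$count == 0L) stop_tcf("empty ROI mask", class = "tcf_empty_roi_error")
  axis <- as.integer(axis)
  spacing <- spacing %||% attr(mask, "spacing") %||% rep(1, 3)
  inplane <- setdiff(1:3, axis)
  ext <- vapply(seq_len(d[axis]), function(s) {
    idx <- switch(axis,
                  `1` = mask$voxels[s, , ],
                  `2` = mask$voxels[, s, ],
                  `3` = mask$voxels[, , s])
    pts <- which(idx, arr.ind = TRUE)
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
    if (nrow(pts) == 0L) return(-Inf)
    if (nrow(pts) == 1L) return(0)
    pts <- sweep(pts, 2, spacing[inplane], `*`)
    # convex hull prunes the O(m^2) diameter scan on big slices
    if (nrow(pts) > 3L) {
      h <- grDevices::chull(pts[, 1], pts[, 2])
      pts <- pts[h, , drop = FALSE]
    }
    max(stats::dist(pts))
  }, numeric(1))
  which.max(ext)  # which.max returns the first (lowest) maximizer
}

#' Extract per-voxel tissue signatures from a masked image
#'
#' Each mask voxel contributes one D-dimensional signature: its normalized
#' intensity across all channels. When the mask exceeds `subsample_cap`, a
#' uniform random subsample of exactly `subsample_cap` voxels is drawn with
#' the given seed (the all-pairs graph stages downstream are quadratic in
#' the node count, so the cap bounds their cost); cap and seed are recorded
#' in the provenance attribute.
#'
#' @param img A normalized [mp_image()].
#' @param mask A [roi_mask()] on the same grid with at least 2 voxels.
#' @param subsample_cap Maximum number of signatures (default 2000).
#' @param seed Seed for the subsample draw.
#' @param include_xy If `TRUE`, append the voxel grid coordinates, scaled to
#'   \[0, 1\], as extra feature channels (off by default: the feature space is
#'   spanned by the imaging channels only).
#' @return An object of class `tissue_signatures`: list with `coords`
#'   (n x ndim integer matrix, 0-based), `features` (n x D matrix),
#'   `channel_names`, `n_voxels`, `D` and `provenance`.
#' @export
extract_signatures <- function(img, mask, subsample_cap = 2000L, seed = NULL,
                               include_xy = FALSE) {
  stopifnot(inherits(img, "mp_image"), inherits(mask, "roi_mask"))
  check_same_grid(img, mask)
  if (!all(img$normalized)) {
    stop_tcf("image must be normalized before signature extraction",
             class = "tcf_precondition_error")
  }
  if (mask$count < 2L) {
    stop_tcf("mask has fewer than 2 voxels", class = "tcf_empty_roi_error")
  }
  if (subsample_cap < 2L) stop_tcf("subsample_cap must be >= 2", class = "tcf_spec_error")
  idx <- which(mask$voxels)
  subsampled <- FALSE
  if (length(idx) > subsample_cap) {
    idx <- with_seed(seed, sort(sample(idx, subsample_cap)))
    subsampled <- TRUE
  }
  coords <- arrayInd(idx, dim(mask$voxels)) - 1L  # 0-based grid coordinates
  feat <- vapply(img$channels, function(ch) ch[idx], numeric(length(idx)))
  feat <- matrix(feat, nrow = length(idx),
                 dimnames = list(NULL, names(img$channels)))
  if (include_xy) {
    sc <- sweep(coords, 2, pmax(dim(mask$voxels) - 1L, 1L), `/`)
    colnames(sc) <- paste0("coord", seq_len(ncol(sc)))
    feat <- cbind(feat, sc)
  }
  structure(list(coords = coords,
                 features = feat,
                 channel_names = colnames(feat),
                 n_voxels = nrow(feat),
                 D = ncol(feat),
                 provenance = list(subsample_cap = subsample_cap,
                                   seed = seed,
                                   subsampled = subsampled,
                                   mask_label = mask$label,
                                   mask_count = mask$count)),
            class = "tissue_signatures")
}

#' @export
print.tissue_signatures <- function(x, ...) {
  cat("<tissue_signatures> n =", x$n_voxels, "| D =", x$D,
      "| channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a channel or array to NIfTI
#'
#' @param data Numeric array, `tcf_channel` or `roi_mask`.
#' @param path Output `.nii` path.
#' @param spacing Voxel spacing to record.
#' @export
write_volume <- function(data, path, spacing = NULL) {
  if (inherits(data, "roi_mask")) {
    spacing <- spacing %||% attr(data, "spacing")
    data <- data$voxels * 1.0
  }
  spacing <- spacing %||% attr(data, "spacing") %||% rep(1, length(dim(data)))
  arr <- array(as.double(data), dim = dim(data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
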