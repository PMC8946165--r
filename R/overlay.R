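# Network-on-anatomy overlays. The renderer rasterizes everything itself
# (nearest-neighbour upscaled background, Bresenham edge segments, colored
# node squares, a color-bar strip) and writes the pixels with png::writePNG,
# so a given input always produces byte-identical output. An optional SVG
# sidecar carries the same primitives in vector form, including the color-bar
# range as text.

#' Overlay rendering options
#'
#' @param background Channel name used as the grayscale backdrop.
#' @param metric Metric name expected on the node map (checked).
#' @param colormap Vector of anchor colors interpolated over the metric range.
#' @param edge_alpha Opacity of edge segments in \[0, 1\].
#' @param node_size Node square half-width in output pixels.
#' @param scale Integer upscaling factor from voxels to pixels.
#' @param fixed_range Color range: `c(0, 1)` is used for centralities,
#'   clustering and strength; `NULL` (data range) for path lengths.
#' @return An `overlay_spec` list.
#' @export
overlay_spec <- function(background, metric,
                         colormap = c("#440154", "#31688E", "#35B779", "#FDE725"),
                         edge_alpha = 0.6, node_size = 2L, scale = 8L,
                         fixed_range = NULL) {
  if (is.null(fixed_range) && metric != "average_path_length") {
    fixed_range <- c(0, 1)
  }
  structure(list(background = background, metric = metric,
                 colormap = colormap, edge_alpha = edge_alpha,
                 node_size = as.integer(node_size), scale = as.integer(scale),
                 fixed_range = fixed_range),
            class = "overlay_spec")
}

# integer Bresenham line between two pixel coordinates
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(xs, ys)
}

metric_colors <- function(values, spec) {
  rng <- spec$fixed_range %||% range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  t <- pmin(pmax((values - rng[1]) / (rng[2] - rng[1]), 0), 1)
  ramp <- grDevices::colorRamp(spec$colormap)
  list(rgb = ramp(t) / 255, range = rng, ramp = ramp)
}

#' Render a connectome overlay on the anatomic image
#'
#' Draws the neighborhood-graph edges (the edges that survive the k-NN /
#' threshold cut-off, before any geodesic computation) as line segments at
#' voxel positions over the grayscale background slice, colors each node by
#' its metric value, appends a color-bar strip, and writes a PNG. Inputs are
#' never modified, and identical inputs give byte-identical files.
#'
#' @param img A [mp_image()] holding the background channel (2D).
#' @param graph A [build_graph()] result whose `node_coords` lie on the image
#'   grid (0-based row/col).
#' @param map A `node_metric_map` covering all graph nodes.
#' @param spec An [overlay_spec()].
#' @param out Output PNG path.
#' @param svg Optional path for an SVG sidecar listing the same primitives
#'   (one `<line>` per edge, one `<circle>` per node) plus the color-bar
#'   range as text.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(img, graph, map, spec, out, svg = NULL) {
  stopifnot(inherits(img, "mp_image"), inherits(graph, "tumor_graph"),
            inherits(map, "node_metric_map"), inherits(spec, "overlay_spec"))
  if (!spec$background %in% names(img$channels)) {
    stop_tcf("background channel '", spec$background, "' not loaded",
             class = "tcf_spec_error")
  }
  if (map$metric_name != spec$metric) {
    stop_tcf("map holds '", map$metric_name, "', spec wants '", spec$metric, "'",
             class = "tcf_spec_error")
  }
  coords <- graph$node_coords
  if (is.null(coords)) stop_tcf("graph has no node coordinates", class = "tcf_geometry_error")
  if (length(map$values) < graph$n_nodes) {
    stop_tcf("metric map does not cover all nodes", class = "tcf_spec_error")
  }
  bg <- img$channels[[spec$background]]
  if (length(dim(bg)) != 2L) stop_tcf("background must be a 2D slice", class = "tcf_spec_error")
  if (any(coords < 0) || any(coords[, 1] >= nrow(bg)) || any(coords[, 2] >= ncol(bg))) {
    stop_tcf("node coordinates fall outside the image grid", class = "tcf_geometry_error")
  }
  bg <- (bg - min(bg)) / max(max(bg) - min(bg), .Machine$double.eps)
  sc <- spec$scale
  big <- bg[rep(seq_len(nrow(bg)), each = sc), rep(seq_len(ncol(bg)), each = sc)]
  h <- nrow(big); wd <- ncol(big)
  bar_w <- 2L * sc
  ras <- array(0, dim = c(h, wd + bar_w, 3))
  for (c3 in 1:3) ras[, seq_len(wd), c3] <- big
  # node pixel centers (row, col)
  px <- coords * sc + floor(sc / 2) + 1L
  edge_col <- c(1, 1, 1)
  a <- spec$edge_alpha
  if (nrow(graph$edges) > 0L) {
    for (e in seq_len(nrow(graph$edges))) {
      p1 <- px[graph$edges$i[e], ]; p2 <- px[graph$edges$j[e], ]
      pts <- bresenham(p1[1], p1[2], p2[1], p2[2])
      for (c3 in 1:3) {
        ras[cbind(pts[, 1], pts[, 2], c3)] <-
          (1 - a) * ras[cbind(pts[, 1], pts[, 2], c3)] + a * edge_col[c3]
      }
    }
  }
  mc <- metric_colors(map$values[seq_len(graph$n_nodes)], spec)
  r <- spec$node_size
  for (v in seq_len(graph$n_nodes)) {
    rr <- pmin(pmax((px[v, 1] - r):(px[v, 1] + r), 1L), h)
    cc <- pmin(pmax((px[v, 2] - r):(px[v, 2] + r), 1L), wd)
    for (c3 in 1:3) ras[rr, cc, c3] <- mc$rgb[v, c3]
  }
  # color-bar strip (top = max of range)
  barv <- seq(1, 0, length.out = h)
  barc <- mc$ramp(barv) / 255
  for (c3 in 1:3) ras[, (wd + 1):(wd + bar_w), c3] <- matrix(barc[, c3], h, bar_w)
  png::writePNG(ras, out)
  if (!is.null(svg)) {
    write_overlay_svg(svg, graph, px, mc, map, c(h, wd + bar_w))
  }
  invisible(out)
}

write_overlay_svg <- function(path, graph, px, mc, map, size) {
  hex <- grDevices::rgb(mc$rgb[, 1], mc$rgb[, 2], mc$rgb[, 3])
  lines <- character(0)
  if (nrow(graph$edges) > 0L) {
    lines <- sprintf(
      '<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="white" stroke-opacity="0.6"/>',
      px[graph$edges$i, 2], px[graph$edges$i, 1],
      px[graph$edges$j, 2], px[graph$edges$j, 1])
  }
  nodes <- sprintf('<circle cx="%d" cy="%d" r="2" fill="%s"/>',
                   px[, 2], px[, 1], hex)
  txt <- sprintf('<text x="2" y="12" font-size="10">%s: %s to %s</text>',
                 map$metric_name, signif(mc$range[1], 3), signif(mc$range[2], 3))
  writeLines(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                       size[2], size[1]),
               lines, nodes, txt, "</svg>"), path)
  invisible(path)
}
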