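# Polygon shape-complexity metrics used to compare mapping products.
# Three scores are computed per patch:
#   Complexity 1 — perimeter/area ratio (1/m);
#   Complexity 2 — 0.8 * ampl * nodes + 0.2 * conv, where ampl is the
#     relative increase of the boundary length over the convex hull and
#     conv the relative area deficit against the hull;
#   Complexity 3 — the node count, summarised at layer level as the mean
#     number of nodes per polygon.
# A crenulated digitized patch scores high on all three; a coarse
# generalised polygon of the same footprint scores low.

#' Complexity 1: perimeter/area ratio
#'
#' @param p a `patch_polygon`.
#' @return ratio in 1/metres; higher for more invaginated patches.
#' @export
complexity1 <- function(p) {
  a <- area(p)
  if (a <= 0) stop("invalid geometry: zero-area polygon")
  perimeter(p) / a
}

#' Relative boundary amplitude
#'
#' `(perimeter - hull perimeter) / perimeter`, computed on the exterior
#' ring against its convex hull; 0 for convex patches, approaching 1 for
#' extremely sinuous boundaries.
#' @param p a `patch_polygon`.
#' @return dimensionless fraction in \[0, 1).
#' @export
boundary_amplitude <- function(p) {
  per <- .ring_length(p$exterior)
  hper <- .ring_length(convex_hull(p)$exterior)
  max(0, (per - hper) / per)
}

#' Convexity deficit
#'
#' `(hull area - area) / hull area` on the exterior ring; 0 for convex
#' patches.
#' @param p a `patch_polygon`.
#' @return dimensionless fraction in \[0, 1).
#' @export
convexity_deficit <- function(p) {
  a <- .ring_signed_area(p$exterior)
  ha <- area(convex_hull(p))
  max(0, (ha - a) / ha)
}

#' Complexity 2: weighted amplitude/node/convexity score
#'
#' `0.8 * ampl * nodes + 0.2 * conv`. Unbounded in the node count by
#' design, so heavily digitized sinuous patches can reach scores in the
#' tens. Zero exactly for convex polygons.
#' @param p a `patch_polygon`.
#' @param exterior_only count exterior-ring nodes only (default `FALSE`:
#'   hole vertices are genuine digitized detail and are counted).
#' @return dimensionless score >= 0.
#' @export
complexity2 <- function(p, exterior_only = FALSE) {
  0.8 * boundary_amplitude(p) * node_count(p, exterior_only = exterior_only) +
    0.2 * convexity_deficit(p)
}

#' Complexity 3: mean node count of a layer
#'
#' The layer-level mean of per-patch node counts.
#' @param layer a `patch_layer` with at least one patch.
#' @return mean nodes per polygon.
#' @export
complexity3 <- function(layer) {
  stopifnot(inherits(layer, "patch_layer"))
  if (!length(layer$patches)) stop("empty layer: no patches to summarise")
  mean(vapply(layer$patches, node_count, 0L))
}

#' Per-patch complexity scores
#'
#' @param layer a `patch_layer`.
#' @return data frame with columns `id`, `area_m2`, `c1`, `ampl`,
#'   `nodes`, `conv`, `c2`.
#' @export
patch_complexity <- function(layer) {
  stopifnot(inherits(layer, "patch_layer"))
  if (!length(layer$patches)) stop("empty layer: no patches to score")
  rows <- lapply(seq_along(layer$patches), function(i) {
    p <- layer$patches[[i]]
    data.frame(id = if (is.null(p$id)) as.character(i) else as.character(p$id),
               area_m2 = area(p), c1 = complexity1(p),
               ampl = boundary_amplitude(p), nodes = node_count(p),
               conv = convexity_deficit(p), c2 = complexity2(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Layer-level complexity summary
#'
#' The per-study summary used to compare mapping products: patch count,
#' mean patch area in hectares, mean Complexity 1 and 2, mean node count
#' (Complexity 3) and the total node count.
#' @param layer a `patch_layer` with at least one patch.
#' @return an object of class `layer_complexity_summary` (a list with
#'   fields `n_patches`, `mean_area_ha`, `mean_c1`, `mean_c2`,
#'   `mean_nodes`, `total_nodes`).
#' @export
summarize_layer <- function(layer) {
  sc <- patch_complexity(layer)
  structure(list(
    n_patches = nrow(sc),
    mean_area_ha = mean(sc$area_m2) / 1e4,
    mean_c1 = mean(sc$c1),
    mean_c2 = mean(sc$c2),
    mean_nodes = mean(sc$nodes),
    total_nodes = as.integer(sum(sc$nodes))
  ), class = "layer_complexity_summary")
}

#' @export
print.layer_complexity_summary <- function(x, ...) {
  cat(sprintf(paste0("Layer complexity: %d patches, mean area %.2f ha\n",
                     "  Complexity 1 (perim/area): %.3f 1/m\n",
                     "  Complexity 2 (ampl/nodes/conv): %.2f\n",
                     "  Complexity 3 (mean nodes): %.1f  (total nodes %d)\n"),
              x$n_patches, x$mean_area_ha, x$mean_c1, x$mean_c2,
              x$mean_nodes, x$total_nodes))
  invisible(x)
}
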