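# Coast-referenced coverage statistics: how mangrove cover is arranged
# with distance from the shoreline, what fraction of the coastline is
# fronted by mangrove, and cover densities per island group.
#
# Patch areas are apportioned to distance bands by dense point sampling
# of each patch (deterministic grid, weights rescaled so every patch
# contributes exactly its true area); distances are exact point-to-
# polyline distances. The discretization error therefore affects only
# the split between adjacent bands, never the total.

# deterministic sample of points covering a patch, with weights summing
# exactly to its area
.patch_area_samples <- function(p, target_points = 400) {
  b <- .bbox(p)
  a <- area(p)
  h <- max(sqrt(a / target_points), 1e-6)
  xs <- seq(b[1L] + h / 2, b[3L], by = h)
  ys <- seq(b[2L] + h / 2, b[4L], by = h)
  if (!length(xs)) xs <- (b[1L] + b[3L]) / 2
  if (!length(ys)) ys <- (b[2L] + b[4L]) / 2
  g <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  keep <- points_in_patch(g, p)
  if (!any(keep)) {  # sliver thinner than the grid: fall back to vertices
    g <- p$exterior
    keep <- rep(TRUE, nrow(g))
  }
  g <- g[keep, , drop = FALSE]
  list(pts = g, w = rep(a / nrow(g), nrow(g)))
}

.layer_distance_samples <- function(layer, coastline, target_points = 400) {
  line <- do.call(rbind, lapply(coastline$polylines, function(m)
    rbind(m, c(NA, NA))))
  line <- line[stats::complete.cases(line), , drop = FALSE]
  out_d <- numeric(0); out_w <- numeric(0)
  for (p in layer$patches) {
    s <- .patch_area_samples(p, target_points)
    dmin <- rep(Inf, nrow(s$pts))
    for (m in coastline$polylines)
      dmin <- pmin(dmin, cpp_point_polyline_dist(s$pts, m))
    out_d <- c(out_d, dmin)
    out_w <- c(out_w, s$w)
  }
  list(d = out_d, w = out_w)
}

#' Cover profile by distance from the coastline
#'
#' Apportions layer cover to half-open distance bands
#' `[0, e1), [e1, e2), ...` from the coastline and reports cumulative
#' cover fractions plus the interpolated distances holding 50% and 90%
#' of the cover.
#' @param layer a `patch_layer` with at least one patch.
#' @param coastline a `coastline_layer` in the same CRS.
#' @param edges strictly increasing band edges in metres (the last edge
#'   is extended to cover any remaining area).
#' @param target_points sampling density per patch (default 400).
#' @return an object of class `distance_band_profile`: data frame
#'   `band_upper_m`, `area_ha`, `cum_fraction`, with attributes `d50`
#'   and `d90` in metres.
#' @export
distance_band_profile <- function(layer, coastline,
                                  edges = c(100, 200, 500, 1000, 2000),
                                  target_points = 400) {
  stopifnot(inherits(layer, "patch_layer"),
            inherits(coastline, "coastline_layer"))
  if (!length(layer$patches)) stop("empty layer: no cover to profile")
  if (any(diff(edges) <= 0) || any(edges <= 0))
    stop("band edges must be positive and strictly increasing")
  s <- .layer_distance_samples(layer, coastline, target_points)
  up <- c(edges, max(edges[length(edges)], max(s$d)) + 1)
  band <- findInterval(s$d, c(0, up), rightmost.closed = FALSE)
  a <- vapply(seq_along(up), function(k) sum(s$w[band == k]), 0)
  cum <- cumsum(a) / sum(a)
  qd <- function(q) {
    # weighted quantile of sampled distances, interpolated
    o <- order(s$d)
    cw <- cumsum(s$w[o]) / sum(s$w)
    stats::approx(cw, s$d[o], xout = q, rule = 2, ties = "ordered")$y
  }
  structure(data.frame(band_upper_m = up, area_ha = a / 1e4,
                       cum_fraction = cum),
            d50 = qd(0.5), d90 = qd(0.9),
            total_ha = sum(a) / 1e4,
            class = c("distance_band_profile", "data.frame"))
}

#' Fraction of coastline fronted by mangrove
#'
#' Percentage of coastline arc length lying within `fronting_dist` of
#' any patch of the layer; the coastline is sampled at `step` metre
#' intervals and each sample carries its arc length.
#' @param layer a `patch_layer`.
#' @param coastline a `coastline_layer`.
#' @param fronting_dist fronting distance in metres (default 50): a
#'   shore point is "protected" when mangrove lies within this range.
#' @param step arc-length sampling step in metres (default 10).
#' @return percentage in \[0, 100\].
#' @export
coastline_protected_fraction <- function(layer, coastline,
                                         fronting_dist = 50, step = 10) {
  stopifnot(inherits(coastline, "coastline_layer"), fronting_dist > 0,
            step > 0)
  tot <- 0; prot <- 0
  for (m in coastline$polylines) {
    seg <- cbind(diff(m[, 1L]), diff(m[, 2L]))
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    L <- cum[length(cum)]
    if (L <= 0) next
    at <- seq(step / 2, L, by = step)
    if (!length(at)) at <- L / 2
    i <- findInterval(at, cum, rightmost.closed = TRUE)
    i[i >= nrow(m)] <- nrow(m) - 1L
    t <- (at - cum[i]) / pmax(len[i], 1e-12)
    pts <- cbind(m[i, 1L] + t * seg[i, 1L], m[i, 2L] + t * seg[i, 2L])
    w <- rep(L / length(at), length(at))
    d <- distance_to_layer(pts, layer)
    tot <- tot + sum(w)
    prot <- prot + sum(w[d <= fronting_dist])
  }
  100 * prot / tot
}

#' Cover density by island group
#'
#' `ha` of cover per `km` of coastline for each group (island or
#' geological-age class).
#' @param cover_ha named numeric vector of cover per group, hectares.
#' @param coastline_km named numeric vector of coastline length per
#'   group, kilometres (same names).
#' @param grouping optional named character vector mapping the names of
#'   `cover_ha` to coarser group labels (e.g. island to age class);
#'   cover and coastline are summed within each group.
#' @return data frame `group`, `cover_ha`, `coastline_km`,
#'   `density_ha_per_km`, ordered as supplied.
#' @export
density_by_group <- function(cover_ha, coastline_km, grouping = NULL) {
  stopifnot(!is.null(names(cover_ha)), !is.null(names(coastline_km)))
  miss <- setdiff(names(cover_ha), names(coastline_km))
  if (length(miss))
    stop("missing coastline for group(s): ", paste(miss, collapse = ", "))
  coastline_km <- coastline_km[names(cover_ha)]
  if (any(coastline_km <= 0)) stop("every group needs coastline > 0")
  if (!is.null(grouping)) {
    g <- grouping[names(cover_ha)]
    cover_ha <- tapply(cover_ha, g, sum)
    coastline_km <- tapply(coastline_km, g, sum)
    cover_ha <- as.numeric(cover_ha[unique(g)])
    names(cover_ha) <- unique(g)
    coastline_km <- as.numeric(coastline_km[names(cover_ha)])
  }
  data.frame(group = names(cover_ha),
             cover_ha = as.numeric(cover_ha),
             coastline_km = as.numeric(coastline_km),
             density_ha_per_km = as.numeric(cover_ha) / as.numeric(coastline_km),
             stringsAsFactors = FALSE)
}
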