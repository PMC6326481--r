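# Planar geometry substrate: patch polygons, layers, coastlines and the
# measurement primitives everything else is built on. All coordinates are
# metres in a projected CRS; geometry is strictly 2-D planar.

.dedupe_ring <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("ring must be an n x 2 matrix of coordinates")
  storage.mode(m) <- "double"
  n <- nrow(m)
  # drop an explicit closing vertex
  if (n > 1L && all(abs(m[1L, ] - m[n, ]) <= tol)) m <- m[-n, , drop = FALSE]
  # drop duplicate consecutive vertices (digitization artefacts)
  n <- nrow(m)
  if (n > 1L) {
    keep <- c(TRUE, rowSums(abs(m[-1L, , drop = FALSE] -
                                m[-n, , drop = FALSE])) > tol)
    m <- m[keep, , drop = FALSE]
  }
  m
}

.ring_signed_area <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(m[, 1L] * m[j, 2L] - m[j, 1L] * m[, 2L]) / 2
}

.ring_length <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(sqrt((m[j, 1L] - m[, 1L])^2 + (m[j, 2L] - m[, 2L])^2))
}

# proper-crossing test for non-adjacent edge pairs of one ring
.ring_is_simple <- function(m) {
  n <- nrow(m)
  if (n < 4L) return(TRUE)
  j <- c(2:n, 1L)
  ax <- m[, 1L]; ay <- m[, 2L]; bx <- m[j, 1L]; by <- m[j, 2L]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    ks <- ks[!(i == 1L & ks == n)]  # skip edges sharing a vertex
    if (!length(ks)) next
    d1 <- cross(ax[ks], ay[ks], bx[ks], by[ks], ax[i], ay[i])
    d2 <- cross(ax[ks], ay[ks], bx[ks], by[ks], bx[i], by[i])
    d3 <- cross(ax[i], ay[i], bx[i], by[i], ax[ks], ay[ks])
    d4 <- cross(ax[i], ay[i], bx[i], by[i], bx[ks], by[ks])
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(FALSE)
  }
  TRUE
}

#' Construct a mangrove patch polygon
#'
#' A patch is a simple planar polygon (one exterior ring, zero or more
#' interior rings/holes) with coordinates in metres. Rings may be given
#' open or closed; the closing vertex and any duplicate consecutive
#' vertices are dropped at ingest. The exterior ring is stored
#' counter-clockwise, holes clockwise.
#'
#' @param exterior n x 2 matrix of exterior-ring vertices (metres).
#' @param holes list of n x 2 matrices, one per interior ring.
#' @param id optional identifier.
#' @param check validate ring simplicity and hole containment (default
#'   `TRUE`; disable only for bulk ingest of pre-validated geometry).
#' @return an object of class `patch_polygon`.
#' @examples
#' sq <- patch_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' area(sq)       # 100
#' perimeter(sq)  # 40
#' @export
patch_polygon <- function(exterior, holes = list(), id = NULL, check = TRUE) {
  ext <- .dedupe_ring(exterior)
  if (nrow(ext) < 3L) stop("invalid geometry: exterior ring has fewer than 3 distinct vertices")
  if (!all(is.finite(ext))) stop("invalid geometry: non-finite coordinates")
  sa <- .ring_signed_area(ext)
  if (abs(sa) <= 0) stop("invalid geometry: zero-area exterior ring")
  if (sa < 0) ext <- ext[nrow(ext):1L, , drop = FALSE]
  hl <- lapply(holes, function(h) {
    h <- .dedupe_ring(h)
    if (nrow(h) < 3L) stop("invalid geometry: hole ring has fewer than 3 distinct vertices")
    if (!all(is.finite(h))) stop("invalid geometry: non-finite coordinates")
    if (.ring_signed_area(h) > 0) h <- h[nrow(h):1L, , drop = FALSE]  # holes CW
    h
  })
  if (check) {
    if (!.ring_is_simple(ext)) stop("invalid geometry: self-intersecting exterior ring")
    for (h in hl) {
      if (!.ring_is_simple(h)) stop("invalid geometry: self-intersecting hole ring")
      if (!all(cpp_points_in_poly(h, list(ext)) == 1L))
        stop("invalid geometry: hole not inside exterior ring")
    }
  }
  structure(list(exterior = ext, holes = hl, id = id),
            class = "patch_polygon")
}

# all rings of a patch (exterior first), the layout the C++ kernels expect
.rings <- function(p) c(list(p$exterior), p$holes)

.bbox <- function(p) {
  xs <- unlist(lapply(.rings(p), function(m) m[, 1L]))
  ys <- unlist(lapply(.rings(p), function(m) m[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' @export
print.patch_polygon <- function(x, ...) {
  cat(sprintf("<patch_polygon%s: %d nodes, %d hole(s), area %.1f m2>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              node_count(x), length(x$holes), area(x)))
  invisible(x)
}

#' Polygon and layer area
#'
#' Shoelace area of the exterior ring minus the area of any holes, in
#' square metres. For a layer, the sum over patches.
#' @param x a `patch_polygon` or `patch_layer`.
#' @param ... unused.
#' @return area in square metres.
#' @export
area <- function(x, ...) UseMethod("area")

#' @export
area.patch_polygon <- function(x, ...) {
  .ring_signed_area(x$exterior) + sum(vapply(x$holes, .ring_signed_area, 0))
}

#' @export
area.patch_layer <- function(x, ...) sum(vapply(x$patches, area, 0))

#' Polygon and layer perimeter
#'
#' Total boundary length: exterior ring plus all hole rings, in metres.
#' @inheritParams area
#' @return perimeter in metres.
#' @export
perimeter <- function(x, ...) UseMethod("perimeter")

#' @export
perimeter.patch_polygon <- function(x, ...) {
  sum(vapply(.rings(x), .ring_length, 0))
}

#' @export
perimeter.patch_layer <- function(x, ...) sum(vapply(x$patches, perimeter, 0))

#' Node count of a patch polygon
#'
#' Number of distinct stored vertices over all rings; the closing vertex
#' of each ring is counted once. With `exterior_only = TRUE` hole
#' vertices are excluded.
#' @param p a `patch_polygon`.
#' @param exterior_only count exterior-ring vertices only.
#' @return integer vertex count.
#' @export
node_count <- function(p, exterior_only = FALSE) {
  stopifnot(inherits(p, "patch_polygon"))
  n <- nrow(p$exterior)
  if (!exterior_only) n <- n + sum(vapply(p$holes, nrow, 0L))
  as.integer(n)
}

#' Convex hull of a patch polygon
#'
#' The smallest convex polygon enclosing all exterior-ring vertices
#' (holes cannot affect the hull).
#' @param p a `patch_polygon`.
#' @return a convex `patch_polygon`.
#' @export
convex_hull <- function(p) {
  stopifnot(inherits(p, "patch_polygon"))
  idx <- grDevices::chull(p$exterior[, 1L], p$exterior[, 2L])
  h <- p$exterior[idx, , drop = FALSE]
  if (nrow(h) < 3L || abs(.ring_signed_area(h)) <= 0)
    stop("invalid geometry: collinear vertices, hull has zero area")
  patch_polygon(h, id = p$id, check = FALSE)
}

#' Construct a patch layer
#'
#' A set of patch polygons tagged with an epoch (calendar year) and the
#' CRS the coordinates are expressed in (must be metric/projected).
#' @param patches list of `patch_polygon` objects.
#' @param epoch calendar-year tag (may be `NA`).
#' @param crs free-text CRS descriptor; must denote a metric projected
#'   system (e.g. `"EPSG:32715"`).
#' @param name free-text layer name.
#' @return an object of class `patch_layer`.
#' @export
patch_layer <- function(patches = list(), epoch = NA, crs = "local-metric",
                        name = "") {
  stopifnot(all(vapply(patches, inherits, TRUE, "patch_polygon")))
  structure(list(patches = patches, epoch = epoch, crs = crs, name = name),
            class = "patch_layer")
}

#' @export
print.patch_layer <- function(x, ...) {
  cat(sprintf("<patch_layer '%s': %d patches, epoch %s, crs %s, %.2f ha>\n",
              x$name, length(x$patches), as.character(x$epoch), x$crs,
              area(x) / 1e4))
  invisible(x)
}

#' @export
length.patch_layer <- function(x) length(x$patches)

#' Minimum-mapping-unit filter
#'
#' Drops every patch whose area is below the minimum mapping unit. The
#' boundary is inclusive: a patch of exactly `mmu` square metres is kept
#' (only patches *smaller* than the MMU are erased).
#' @param layer a `patch_layer`.
#' @param mmu minimum mapping unit in square metres (default 10).
#' @return the filtered `patch_layer`.
#' @export
mmu_filter <- function(layer, mmu = 10) {
  stopifnot(inherits(layer, "patch_layer"), mmu > 0)
  keep <- vapply(layer$patches, area, 0) >= mmu
  layer$patches <- layer$patches[keep]
  layer
}

#' Construct a coastline layer
#'
#' One or more ordered vertex chains (polylines) in metres.
#' @param lines an n x 2 matrix or a list of such matrices.
#' @return an object of class `coastline_layer` with derived
#'   `total_length` in metres.
#' @export
coastline_layer <- function(lines) {
  if (is.matrix(lines)) lines <- list(lines)
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L) stop("polyline must be an n x 2 matrix, n >= 2")
    if (!all(is.finite(m))) stop("non-finite coastline coordinates")
    m
  })
  seglen <- function(m) {
    n <- nrow(m)
    sum(sqrt(diff(m[, 1L])^2 + diff(m[, 2L])^2))
  }
  tl <- sum(vapply(lines, seglen, 0))
  if (tl <= 0) stop("coastline has zero total length")
  structure(list(polylines = lines, total_length = tl),
            class = "coastline_layer")
}

#' @export
print.coastline_layer <- function(x, ...) {
  cat(sprintf("<coastline_layer: %d polyline(s), %.2f km>\n",
              length(x$polylines), x$total_length / 1e3))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Overlay / distance wrappers around the C++ kernels
# ---------------------------------------------------------------------------

#' Area of intersection of two patch polygons
#'
#' Exact (to floating point) planar intersection area, holes respected,
#' computed by signed fan-triangulation and convex clipping.
#' @param p,q `patch_polygon` objects.
#' @return intersection area in square metres.
#' @export
intersection_area <- function(p, q) {
  bp <- .bbox(p); bq <- .bbox(q)
  if (bp[3L] <= bq[1L] || bq[3L] <= bp[1L] ||
      bp[4L] <= bq[2L] || bq[4L] <= bp[2L]) return(0)
  max(0, cpp_poly_inter_area(.rings(p), .rings(q)))
}

#' Minimum distance between two patch polygons
#'
#' Boundary-to-boundary Euclidean distance; zero when the polygons
#' touch, cross, or one contains the other.
#' @param p,q `patch_polygon` objects.
#' @return distance in metres.
#' @export
patch_distance <- function(p, q) cpp_poly_min_dist(.rings(p), .rings(q))

#' Point-in-patch test
#'
#' Even-odd containment with boundary points counted as inside.
#' @param pts n x 2 matrix of point coordinates (metres).
#' @param p a `patch_polygon`.
#' @return logical vector of length n.
#' @export
points_in_patch <- function(pts, p) {
  pts <- as.matrix(pts); storage.mode(pts) <- "double"
  cpp_points_in_poly(pts, .rings(p)) == 1L
}

#' Classify points against a layer
#'
#' `TRUE` where a point lies inside (or on the boundary of) any patch.
#' @param pts n x 2 matrix of point coordinates.
#' @param layer a `patch_layer`.
#' @return logical vector of length n.
#' @export
points_in_layer <- function(pts, layer) {
  pts <- as.matrix(pts); storage.mode(pts) <- "double"
  out <- rep(FALSE, nrow(pts))
  for (p in layer$patches) {
    todo <- which(!out)
    if (!length(todo)) break
    b <- .bbox(p)
    cand <- todo[pts[todo, 1L] >= b[1L] & pts[todo, 1L] <= b[3L] &
                 pts[todo, 2L] >= b[2L] & pts[todo, 2L] <= b[4L]]
    if (!length(cand)) next
    out[cand] <- cpp_points_in_poly(pts[cand, , drop = FALSE], .rings(p)) == 1L
  }
  out
}

#' Distance from points to the nearest patch of a layer
#'
#' Zero for points inside a patch, else the Euclidean distance to the
#' nearest patch boundary.
#' @inheritParams points_in_layer
#' @return numeric vector of distances in metres.
#' @export
distance_to_layer <- function(pts, layer) {
  pts <- as.matrix(pts); storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (!length(layer$patches)) return(rep(Inf, n))
  best <- rep(Inf, n)
  inside <- points_in_layer(pts, layer)
  best[inside] <- 0
  todo <- which(!inside)
  if (length(todo)) {
    for (p in layer$patches) {
      for (m in .rings(p)) {
        ring <- rbind(m, m[1L, ])
        d <- cpp_point_polyline_dist(pts[todo, , drop = FALSE], ring)
        best[todo] <- pmin(best[todo], d)
      }
    }
  }
  best
}

#' Rigidly translate a patch polygon
#' @param p a `patch_polygon`.
#' @param shift length-2 numeric `(dx, dy)` in metres.
#' @return translated `patch_polygon`.
#' @export
translate_patch <- function(p, shift) {
  stopifnot(length(shift) == 2L, all(is.finite(shift)))
  p$exterior <- sweep(p$exterior, 2L, shift, "+")
  p$holes <- lapply(p$holes, function(m) sweep(m, 2L, shift, "+"))
  p
}

#' Scale a patch polygon about a fixed point
#'
#' Uniform scaling about `centre`; used by the synthetic change script
#' to expand/contract star-shaped patches so that the scaled polygon
#' nests exactly inside (or around) the original.
#' @param p a `patch_polygon`.
#' @param factor positive scale factor applied to coordinates (area
#'   scales by `factor^2`).
#' @param centre length-2 fixed point; default the exterior-ring vertex
#'   centroid.
#' @return scaled `patch_polygon`.
#' @export
scale_patch <- function(p, factor, centre = colMeans(p$exterior)) {
  stopifnot(factor > 0, length(centre) == 2L)
  sc <- function(m) sweep(sweep(m, 2L, centre, "-") * factor, 2L, centre, "+")
  p$exterior <- sc(p$exterior)
  p$holes <- lapply(p$holes, sc)
  p
}
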