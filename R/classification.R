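# Semi-automatic classification chains over georeferenced reflectance
# grids. Three chains are provided, mirroring common practice for RGB
# coastal imagery:
#   MLC1   — Gaussian maximum-likelihood over the whole scene;
#   MLC2   — the same classifier applied separately to the land and sea
#            sides of the coastline (side-specific class sets);
#   HYBRID — NDVI-masked region-growing segmentation, keeping segments
#            that intersect the MLC2 mangrove class.
# Classified rasters are converted to patch polygons and passed through
# the minimum-mapping-unit filter.

#' Construct a spectral scene
#'
#' A georeferenced stack of equally shaped band grids. The georeference
#' is a north-up affine: pixel `(i, j)` (row, column, 1-based) covers
#' `x in [x0 + (j-1) res, x0 + j res]`, `y in [ytop - i res,
#' ytop - (i-1) res]`.
#'
#' @param bands named list of numeric matrices; names typically among
#'   `R`, `G`, `B`, `NIR`.
#' @param origin length-2 numeric `(x0, ytop)`: map coordinates of the
#'   top-left corner, metres.
#' @param res square pixel size in metres.
#' @param nodata optional logical matrix marking no-data pixels.
#' @return an object of class `spectral_scene`.
#' @export
spectral_scene <- function(bands, origin = c(0, 0), res = 1, nodata = NULL) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)),
            res > 0, length(origin) == 2L)
  dm <- dim(bands[[1L]])
  for (b in bands)
    if (!is.matrix(b) || !all(dim(b) == dm))
      stop("all bands must be matrices of identical shape")
  if (is.null(nodata)) nodata <- matrix(FALSE, dm[1L], dm[2L])
  stopifnot(all(dim(nodata) == dm))
  structure(list(bands = bands, origin = as.numeric(origin), res = res,
                 nodata = nodata, dim = dm),
            class = "spectral_scene")
}

#' @export
print.spectral_scene <- function(x, ...) {
  cat(sprintf("<spectral_scene: %d x %d px, %.1f m, bands %s>\n",
              x$dim[1L], x$dim[2L], x$res,
              paste(names(x$bands), collapse = ",")))
  invisible(x)
}

# map coordinates of all pixel centres, row-major like `which()`
pixel_centers <- function(scene) {
  nr <- scene$dim[1L]; nc <- scene$dim[2L]
  i <- rep(seq_len(nr), times = nc)
  j <- rep(seq_len(nc), each = nr)
  cbind(x = scene$origin[1L] + (j - 0.5) * scene$res,
        y = scene$origin[2L] - (i - 0.5) * scene$res)
}

#' Normalized difference vegetation index
#'
#' `(NIR - R) / (NIR + R)` per pixel, in \[-1, 1\]; `NA` where the
#' denominator is zero or the pixel is no-data.
#' @param scene a `spectral_scene` with `NIR` and `R` bands.
#' @return numeric matrix.
#' @export
ndvi <- function(scene) {
  if (is.null(scene$bands$NIR)) stop("missing band: NIR is required for NDVI")
  if (is.null(scene$bands$R)) stop("missing band: R is required for NDVI")
  nir <- scene$bands$NIR; r <- scene$bands$R
  denom <- nir + r
  out <- (nir - r) / denom
  out[denom == 0 | scene$nodata] <- NA_real_
  out
}

#' Vegetation mask from an NDVI grid
#'
#' `TRUE` where NDVI is at or above the threshold (the inclusive 0.2
#' cut separates vegetated from non-vegetated cover).
#' @param ndvi_grid numeric matrix of NDVI values.
#' @param threshold inclusive threshold (default 0.2).
#' @return logical matrix (`NA` input pixels are `FALSE`).
#' @export
vegetation_mask <- function(ndvi_grid, threshold = 0.2) {
  out <- !is.na(ndvi_grid) & ndvi_grid >= threshold
  out
}

#' Land/sea mask from a coastline polyline
#'
#' Splits non-no-data pixels by which side of the coastline their
#' centre falls on (pixel-centre rule). The side containing
#' `land_point` is labelled land.
#' @param scene a `spectral_scene`.
#' @param coastline a `coastline_layer` (first polyline used).
#' @param land_point length-2 coordinates of any point known to lie on
#'   land.
#' @return logical matrix, `TRUE` = land.
#' @export
land_sea_mask <- function(scene, coastline, land_point) {
  stopifnot(inherits(coastline, "coastline_layer"), length(land_point) == 2L)
  line <- coastline$polylines[[1L]]
  ref <- cpp_polyline_side(matrix(as.numeric(land_point), 1L, 2L), line)
  if (ref[1L] == 0L) stop("land_point lies exactly on the coastline")
  side <- cpp_polyline_side(pixel_centers(scene), line)
  matrix(side == ref[1L], scene$dim[1L], scene$dim[2L])
}

#' Assemble a training set from labelled pixels
#'
#' @param scene a `spectral_scene`.
#' @param regions named list (one entry per class) of pixel index
#'   vectors (positions into the band matrices) or n x 2 matrices of
#'   `(row, col)` indices.
#' @return a `training_set`: named list of n x d band-value matrices.
#' @export
training_from_regions <- function(scene, regions) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  d <- length(scene$bands)
  out <- lapply(regions, function(idx) {
    if (is.matrix(idx)) idx <- (idx[, 2L] - 1L) * scene$dim[1L] + idx[, 1L]
    m <- vapply(scene$bands, function(b) b[idx], numeric(length(idx)))
    if (!is.matrix(m)) m <- matrix(m, nrow = length(idx))
    colnames(m) <- names(scene$bands)
    m
  })
  structure(out, class = "training_set")
}

#' Fit a Gaussian maximum-likelihood class model
#'
#' Per-class multivariate Gaussian by sample mean and covariance;
#' near-singular covariances are ridge-regularized. Classes appearing
#' more than once are merged before fitting. Priors default to equal.
#' @param training a `training_set` (named list of n x d pixel-value
#'   matrices).
#' @param priors optional named numeric vector of class priors (renormalized
#'   to sum to 1).
#' @param ridge ridge added to the covariance diagonal when it is not
#'   positive-definite (default `1e-8` times the mean band variance).
#' @return an object of class `class_model`.
#' @export
mlc_train <- function(training, priors = NULL, ridge = NULL) {
  cls <- unique(names(training))
  merged <- lapply(cls, function(k)
    do.call(rbind, unname(training[names(training) == k])))
  names(merged) <- cls
  d <- ncol(merged[[1L]])
  models <- lapply(merged, function(m) {
    if (nrow(m) < d + 1L)
      stop("insufficient training: a class has fewer than d+1 pixels")
    mu <- colMeans(m)
    S <- stats::cov(m)
    eps <- if (is.null(ridge)) 1e-8 * mean(diag(S)) else ridge
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      S <- S + diag(max(eps, 1e-12), d)
      ch <- chol(S)
    }
    list(mean = mu, chol = ch, logdet = 2 * sum(log(diag(ch))))
  })
  if (is.null(priors)) priors <- setNames(rep(1 / length(cls), length(cls)), cls)
  priors <- priors[cls] / sum(priors[cls])
  structure(list(classes = cls, models = models, priors = priors, d = d),
            class = "class_model")
}

#' Gaussian maximum-likelihood classification
#'
#' Assigns every (non-masked, non-no-data) pixel to the class with the
#' highest Gaussian log-likelihood plus log prior. Ties break
#' deterministically in alphabetical class order. Without a mask this
#' is the plain whole-scene chain (MLC1).
#' @param scene a `spectral_scene`.
#' @param model a `class_model` from [mlc_train()].
#' @param mask optional logical matrix; only `TRUE` pixels are
#'   classified.
#' @return character matrix of class labels (`NA` where skipped).
#' @export
mlc_classify <- function(scene, model, mask = NULL) {
  stopifnot(inherits(model, "class_model"))
  nr <- scene$dim[1L]; nc <- scene$dim[2L]
  use <- !scene$nodata
  if (!is.null(mask)) use <- use & mask
  idx <- which(use)
  out <- matrix(NA_character_, nr, nc)
  if (!length(idx)) return(out)
  X <- vapply(scene$bands, function(b) b[idx], numeric(length(idx)))
  if (!is.matrix(X)) X <- matrix(X, nrow = length(idx))
  cls <- sort(model$classes)  # alphabetical tie-break order
  ll <- matrix(NA_real_, length(idx), length(cls))
  for (k in seq_along(cls)) {
    m <- model$models[[cls[k]]]
    ctr <- sweep(X, 2L, m$mean)
    z <- backsolve(m$chol, t(ctr), transpose = TRUE)
    ll[, k] <- -0.5 * (colSums(z^2) + m$logdet) +
      log(model$priors[[cls[k]]])
  }
  out[idx] <- cls[max.col(ll, ties.method = "first")]
  out
}

#' Land/sea partitioned maximum-likelihood chain (MLC2)
#'
#' Classifies the land and sea sides of the coastline separately, each
#' with its own class set, and merges the two label grids.
#' @param scene a `spectral_scene`.
#' @param land_model,sea_model `class_model` objects for the two sides.
#' @param land logical matrix from [land_sea_mask()] (`TRUE` = land).
#' @return character matrix of class labels.
#' @export
mlc_classify_partitioned <- function(scene, land_model, sea_model, land) {
  out <- mlc_classify(scene, land_model, mask = land)
  sea <- mlc_classify(scene, sea_model, mask = !land)
  out[is.na(out)] <- sea[is.na(out)]
  out
}

#' Region-growing segmentation
#'
#' Grows 4-connected segments of spectrally similar pixels inside a
#' mask: a pixel joins the segment when its Euclidean distance to the
#' running segment mean, in band space normalized to \[0, 1\], is at
#' most `diff_threshold`. Segments smaller than `min_size_px` are then
#' merged into their most spectrally similar neighbour. The result is a
#' partition of the mask.
#' @param scene a `spectral_scene`.
#' @param mask logical matrix of pixels to segment.
#' @param diff_threshold similarity threshold (default 0.75).
#' @param min_size_px minimum segment size in pixels (default 750;
#'   scale it with the scene when working on small scenes).
#' @return integer matrix of segment labels (0 outside the mask).
#' @export
region_grow_segment <- function(scene, mask, diff_threshold = 0.75,
                                min_size_px = 750) {
  stopifnot(diff_threshold > 0, min_size_px > 0)
  mask <- mask & !scene$nodata
  if (!any(mask)) return(matrix(0L, scene$dim[1L], scene$dim[2L]))
  norm <- lapply(scene$bands, function(b) {
    v <- b[mask]
    rng <- range(v, finite = TRUE)
    if (diff(rng) == 0) return(b * 0)
    (b - rng[1L]) / diff(rng)
  })
  lab <- cpp_region_grow(norm, mask, diff_threshold)
  .merge_small_segments(lab, norm, mask, min_size_px)
}

.merge_small_segments <- function(lab, bands, mask, min_size_px) {
  repeat {
    ids <- sort(unique(lab[mask]))
    sizes <- tabulate(lab[mask], nbins = max(ids))
    small <- ids[sizes[ids] < min_size_px]
    if (!length(small) || length(ids) == 1L) break
    # segment means per band
    means <- vapply(bands, function(b)
      as.numeric(tapply(b[mask], lab[mask], mean))[match(ids, sort(unique(lab[mask])))],
      numeric(length(ids)))
    if (!is.matrix(means)) means <- matrix(means, nrow = length(ids))
    rownames(means) <- ids
    # adjacency between labels (4-neighbour pairs)
    nr <- nrow(lab)
    a <- cbind(as.vector(lab[-nr, ]), as.vector(lab[-1L, ]))
    b2 <- cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1L]))
    prs <- rbind(a, b2)
    prs <- prs[prs[, 1L] > 0 & prs[, 2L] > 0 & prs[, 1L] != prs[, 2L], ,
               drop = FALSE]
    if (!nrow(prs)) break
    prs <- unique(rbind(prs, prs[, 2:1, drop = FALSE]))
    changed <- FALSE
    for (s in small) {
      nb <- unique(prs[prs[, 1L] == s, 2L])
      nb <- setdiff(nb, s)
      if (!length(nb)) next
      dm <- means[as.character(nb), , drop = FALSE]
      dd <- sqrt(rowSums(sweep(dm, 2L, means[as.character(s), ])^2))
      tgt <- nb[which.min(dd)]
      lab[lab == s] <- tgt
      changed <- TRUE
    }
    if (!changed) break
  }
  # renumber 1..k
  ids <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, ids, nomatch = 0L)
  lab
}

#' Select segments intersecting a class mask
#'
#' Any-overlap rule: a segment is selected whole as soon as one of its
#' pixels overlaps the (MLC2 mangrove) mask.
#' @param segments integer matrix of segment labels (0 = background).
#' @param class_mask logical matrix, co-registered with `segments`.
#' @return logical matrix: union of all selected segments.
#' @export
hybrid_select <- function(segments, class_mask) {
  stopifnot(all(dim(segments) == dim(class_mask)))
  hit <- unique(segments[class_mask & segments > 0])
  matrix(segments %in% hit & segments > 0, nrow(segments), ncol(segments))
}

#' Convert a classified raster to patch polygons
#'
#' Traces the 4-connected components of one class into polygons (holes
#' preserved) in map units, then applies the minimum-mapping-unit
#' filter. 4-connectivity avoids diagonal leaks that would create
#' self-touching rings across corners.
#' @param labels character/integer matrix of class labels (or a logical
#'   matrix with `class = TRUE`).
#' @param class the class value to trace.
#' @param origin,res georeference as in [spectral_scene()].
#' @param mmu minimum mapping unit in square metres (default 10).
#' @param epoch,crs,name metadata passed to [patch_layer()].
#' @return a `patch_layer`.
#' @export
raster_to_patches <- function(labels, class, origin = c(0, 0), res = 1,
                              mmu = 10, epoch = NA, crs = "local-metric",
                              name = "") {
  mask <- !is.na(labels) & labels == class
  comp <- cpp_label_components(mask)
  k <- max(comp)
  patches <- vector("list", k)
  for (cid in seq_len(k))
    patches[[cid]] <- .trace_component(comp == cid, origin, res,
                                       id = as.character(cid))
  mmu_filter(patch_layer(patches, epoch = epoch, crs = crs, name = name),
             mmu = mmu)
}

# Trace the boundary of one 4-connected pixel component into a
# patch_polygon. Directed unit edges are emitted with the interior on
# the left; loops with positive signed area are exteriors, negative are
# holes. At pinch vertices the leftmost turn is taken, which keeps each
# loop simple.
.trace_component <- function(mask, origin, res, id = NULL) {
  cells <- which(mask, arr.ind = TRUE)
  i0 <- min(cells[, 1L]) - 1L; j0 <- min(cells[, 2L]) - 1L
  li <- cells[, 1L] - i0; lj <- cells[, 2L] - j0
  nrl <- max(li); ncl <- max(lj)
  sub <- matrix(FALSE, nrl + 2L, ncl + 2L)  # padded local mask
  sub[cbind(li + 1L, lj + 1L)] <- TRUE
  inm <- function(i, j) sub[cbind(i + 1L, j + 1L)]
  key <- function(i, j) i * (ncl + 1L) + j  # node (i,j), i,j from 0
  from <- integer(0); to <- integer(0)
  # per cell (li, lj): corners BL=(i, j-1) BR=(i, j) TR=(i-1, j) TL=(i-1, j-1)
  b <- !inm(li + 1L, lj); if (any(b)) { from <- c(from, key(li[b], lj[b] - 1L)); to <- c(to, key(li[b], lj[b])) }
  r <- !inm(li, lj + 1L); if (any(r)) { from <- c(from, key(li[r], lj[r])); to <- c(to, key(li[r] - 1L, lj[r])) }
  t2 <- !inm(li - 1L, lj); if (any(t2)) { from <- c(from, key(li[t2] - 1L, lj[t2])); to <- c(to, key(li[t2] - 1L, lj[t2] - 1L)) }
  l <- !inm(li, lj - 1L); if (any(l)) { from <- c(from, key(li[l] - 1L, lj[l] - 1L)); to <- c(to, key(li[l], lj[l] - 1L)) }
  ne <- length(from)
  out_edges <- split(seq_len(ne), from)
  used <- rep(FALSE, ne)
  nodexy <- function(k2) cbind(k2 %% (ncl + 1L), k2 %/% (ncl + 1L))  # (j, i)
  dirvec <- function(e) {
    a <- nodexy(from[e]); b2 <- nodexy(to[e])
    c(b2[1L] - a[1L], -(b2[2L] - a[2L]))  # map-space direction (y up)
  }
  rings <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    ring_nodes <- integer(0)
    e <- e0
    start <- from[e0]
    repeat {
      used[e] <- TRUE
      ring_nodes <- c(ring_nodes, from[e])
      if (to[e] == start) break  # loop closed (guards pinch vertices)
      nxt <- out_edges[[as.character(to[e])]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      if (length(nxt) > 1L) {
        d1 <- dirvec(e)
        score <- vapply(nxt, function(e2) {
          d2 <- dirvec(e2)
          atan2(d1[1L] * d2[2L] - d1[2L] * d2[1L],
                d1[1L] * d2[1L] + d1[2L] * d2[2L])
        }, 0)
        nxt <- nxt[which.max(score)]  # leftmost turn
      } else nxt <- nxt[1L]
      e <- nxt
    }
    jj <- ring_nodes %% (ncl + 1L); ii <- ring_nodes %/% (ncl + 1L)
    x <- origin[1L] + (j0 + jj) * res
    y <- origin[2L] - (i0 + ii) * res
    rings[[length(rings) + 1L]] <- .simplify_collinear(cbind(x, y))
  }
  sa <- vapply(rings, .ring_signed_area, 0)
  ext <- rings[[which.max(sa)]]
  holes <- rings[sa < 0]
  patch_polygon(ext, holes = holes, id = id, check = FALSE)
}

.simplify_collinear <- function(m, tol = 1e-9) {
  n <- nrow(m)
  if (n <= 3L) return(m)
  prev <- rbind(m[n, ], m[-n, ])
  nxt <- rbind(m[-1L, ], m[1L, ])
  cr <- (m[, 1L] - prev[, 1L]) * (nxt[, 2L] - prev[, 2L]) -
        (m[, 2L] - prev[, 2L]) * (nxt[, 1L] - prev[, 1L])
  keep <- abs(cr) > tol
  if (sum(keep) < 3L) return(m)
  m[keep, , drop = FALSE]
}
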