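# Spatio-temporal analysis of moving polygons between two epochs.
# Patches from both epochs are grouped when their boundaries lie within
# a distance threshold (default 15 m); within a group the footprint is
# split by area into STB (stable, present in both epochs), CON
# (contraction, epoch-t only) and EXP (expansion, epoch-t1 only), while
# groups with patches from a single epoch yield GEN (generation, new in
# t1) or DIS (disappearance, gone after t) events. Patches within one
# epoch are assumed non-overlapping, as digitized map products are.

STAMP_CATEGORIES <- c("STB", "EXP", "CON", "GEN", "DIS")

#' STAMP change events between two epochs
#'
#' @param layer_t,layer_t1 `patch_layer` objects for epochs t and t+d,
#'   in the same CRS.
#' @param dist_threshold boundary-to-boundary grouping distance in
#'   metres (default 15).
#' @return an object of class `stamp_events`: a data frame with columns
#'   `group`, `category` (one of STB/EXP/CON/GEN/DIS), `area_m2`, and a
#'   `geoms` attribute holding, per group, the participating epoch
#'   polygons. Category areas satisfy the conservation identities
#'   `area(t) = STB + CON + DIS` and `area(t1) = STB + EXP + GEN`.
#' @export
stamp_events <- function(layer_t, layer_t1, dist_threshold = 15) {
  stopifnot(inherits(layer_t, "patch_layer"), inherits(layer_t1, "patch_layer"),
            dist_threshold >= 0)
  if (!identical(layer_t$crs, layer_t1$crs))
    stop("reference-system mismatch: epochs are in different CRSs")
  pt <- layer_t$patches; p1 <- layer_t1$patches
  n1 <- length(pt); n2 <- length(p1)
  all_p <- c(pt, p1)
  n <- n1 + n2
  # union-find over boundary-distance contiguity
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  if (n > 1L) {
    bb <- t(vapply(all_p, .bbox, numeric(4)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (bb[i, 1L] > bb[j, 3L] + dist_threshold ||
          bb[j, 1L] > bb[i, 3L] + dist_threshold ||
          bb[i, 2L] > bb[j, 4L] + dist_threshold ||
          bb[j, 2L] > bb[i, 4L] + dist_threshold) next
      if (patch_distance(all_p[[i]], all_p[[j]]) <= dist_threshold)
        unite(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  rows <- list(); geoms <- list()
  gid <- 0L
  for (g in groups) {
    gid <- gid + 1L
    it <- g[g <= n1]; i1 <- g[g > n1]
    at <- sum(vapply(all_p[it], area, 0))
    a1 <- sum(vapply(all_p[i1], area, 0))
    if (!length(it)) {
      rows[[length(rows) + 1L]] <- data.frame(group = gid, category = "GEN",
                                              area_m2 = a1)
    } else if (!length(i1)) {
      rows[[length(rows) + 1L]] <- data.frame(group = gid, category = "DIS",
                                              area_m2 = at)
    } else {
      stb <- 0
      for (a in all_p[it]) for (b in all_p[i1]) stb <- stb + intersection_area(a, b)
      stb <- min(stb, at, a1)  # clamp float residue
      rows[[length(rows) + 1L]] <- data.frame(
        group = gid, category = c("STB", "CON", "EXP"),
        area_m2 = c(stb, at - stb, a1 - stb))
    }
    geoms[[gid]] <- list(t = all_p[it], t1 = all_p[i1])
  }
  ev <- do.call(rbind, rows)
  ev <- ev[ev$area_m2 > 0 | ev$category == "STB", , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, geoms = geoms,
            epochs = c(layer_t$epoch, layer_t1$epoch),
            class = c("stamp_events", "data.frame"))
}

#' Summarise STAMP events per category
#'
#' Category totals in hectares and per kilometre of coastline, plus the
#' implied epoch covers and percentage change.
#' @param events a `stamp_events` object.
#' @param coastline a `coastline_layer` (normalising denominator).
#' @return an object of class `change_summary`: list with `per_category`
#'   (data frame `category`, `area_ha`, `ha_per_km`), `area_t_ha`,
#'   `area_t1_ha`, `increase_pct`.
#' @export
change_summary <- function(events, coastline) {
  stopifnot(inherits(events, "stamp_events"),
            inherits(coastline, "coastline_layer"))
  km <- coastline$total_length / 1e3
  if (km <= 0) stop("zero-length coastline")
  tot <- vapply(STAMP_CATEGORIES, function(k)
    sum(events$area_m2[events$category == k]) / 1e4, 0)
  at <- tot[["STB"]] + tot[["CON"]] + tot[["DIS"]]
  a1 <- tot[["STB"]] + tot[["EXP"]] + tot[["GEN"]]
  structure(list(
    per_category = data.frame(category = STAMP_CATEGORIES,
                              area_ha = as.numeric(tot),
                              ha_per_km = as.numeric(tot) / km,
                              stringsAsFactors = FALSE),
    area_t_ha = at, area_t1_ha = a1,
    increase_pct = cover_increase_pct(at, a1),
    coastline_km = km
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("Change summary over %.1f km of coastline:\n", x$coastline_km))
  print(x$per_category, row.names = FALSE)
  cat(sprintf("cover %.1f ha -> %.1f ha (%+.1f%%)\n",
              x$area_t_ha, x$area_t1_ha, x$increase_pct))
  invisible(x)
}

#' Percentage change in cover between two epochs
#'
#' `100 * (cover_t1 - cover_t) / cover_t`.
#' @param cover_t,cover_t1 covers in any common unit.
#' @return percentage change.
#' @export
cover_increase_pct <- function(cover_t, cover_t1) {
  stopifnot(cover_t > 0)
  100 * (cover_t1 - cover_t) / cover_t
}

#' Two-sample Kolmogorov-Smirnov comparison of patch-size samples
#'
#' `D = sup |ECDF1 - ECDF2|` with the asymptotic p-value.
#' @param sizes_t,sizes_t1 numeric vectors of patch areas for the two
#'   epochs.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(sizes_t, sizes_t1) {
  if (!length(sizes_t) || !length(sizes_t1)) stop("empty sample")
  # own sup-difference of the two ECDFs
  xs <- sort(unique(c(sizes_t, sizes_t1)))
  e1 <- vapply(xs, function(v) mean(sizes_t <= v), 0)
  e2 <- vapply(xs, function(v) mean(sizes_t1 <= v), 0)
  D <- max(abs(e1 - e2))
  kt <- suppressWarnings(stats::ks.test(sizes_t, sizes_t1, exact = FALSE))
  list(D = D, p_value = kt$p.value)
}

#' Rigidly shift an epoch layer
#'
#' Translation applied before change analysis to correct known imagery
#' positioning offsets between epochs (the shift is estimated
#' externally from stable features). Areas and complexity scores are
#' unchanged.
#' @param layer a `patch_layer`.
#' @param shift length-2 numeric `(dx, dy)` in metres.
#' @return shifted `patch_layer`.
#' @export
align_epochs <- function(layer, shift) {
  stopifnot(inherits(layer, "patch_layer"), length(shift) == 2L,
            all(is.finite(shift)))
  layer$patches <- lapply(layer$patches, translate_patch, shift = shift)
  layer
}
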