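# Readers and writers for the plain-text exchange formats: GeoJSON
# (RFC 7946) and WKT for vector layers, ESRI ASCII grid for rasters,
# JSON/CSV reports, and KML reading (via the optional xml2 backend)
# with a transverse-Mercator projection for lon/lat input. All
# analysis happens in a metric projected CRS; geographic coordinates
# are only accepted at the I/O boundary together with a projection
# target.

.close_ring <- function(m) rbind(m, m[1L, , drop = FALSE])

.patch_to_geojson <- function(p) {
  rings <- lapply(.rings(p), function(m) {
    mm <- .close_ring(m)
    lapply(seq_len(nrow(mm)), function(i) c(mm[i, 1L], mm[i, 2L]))
  })
  list(type = "Feature",
       properties = list(id = if (is.null(p$id)) NULL else as.character(p$id)),
       geometry = list(type = "Polygon", coordinates = rings))
}

#' Write a patch layer or coastline to GeoJSON
#'
#' @param x a `patch_layer` or `coastline_layer`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  if (inherits(x, "patch_layer")) {
    feats <- lapply(x$patches, .patch_to_geojson)
    fc <- list(type = "FeatureCollection",
               properties = list(epoch = x$epoch, crs = x$crs, name = x$name),
               features = feats)
  } else if (inherits(x, "coastline_layer")) {
    feats <- lapply(x$polylines, function(m) {
      list(type = "Feature", properties = list(),
           geometry = list(
             type = "LineString",
             coordinates = lapply(seq_len(nrow(m)),
                                  function(i) c(m[i, 1L], m[i, 2L]))))
    })
    fc <- list(type = "FeatureCollection", properties = list(kind = "coastline"),
               features = feats)
  } else stop("unsupported object for GeoJSON output")
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(pt) as.numeric(unlist(pt)[1:2])))
}

#' Read a GeoJSON vector file
#'
#' Polygons/MultiPolygons become a `patch_layer` (geometry validated
#' and deduplicated at ingest); LineString features become a
#' `coastline_layer`. Coordinates must already be metric; files that
#' look geographic (all |x| <= 360 and |y| <= 90) are refused unless a
#' `project` function is supplied.
#' @param path file path.
#' @param project optional function `(matrix lon/lat) -> matrix x/y`
#'   applied to every coordinate (see [utm_project()]).
#' @param epoch,crs,name metadata for the resulting layer (defaults
#'   from the file where present).
#' @return `patch_layer` or `coastline_layer`.
#' @export
read_geojson <- function(path, project = NULL, epoch = NULL, crs = NULL,
                         name = NULL) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("format error: cannot parse GeoJSON: ",
                                          conditionMessage(e)))
  if (is.null(gj$type)) stop("format error: not a GeoJSON object")
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else list(list(type = "Feature", properties = list(), geometry = gj))
  geoms <- lapply(feats, function(f) f$geometry)
  types <- vapply(geoms, function(g) g$type %||% "", "")
  tr <- function(m) {
    m <- .maybe_project(m, project)
    m
  }
  file_crs <- (gj$properties %||% list())$crs %||% gj$crs$properties$name
  if (.is_geographic_crs(file_crs) && is.null(project))
    stop("CRS error: file is in a geographic CRS (", file_crs,
         "); supply a `project` function (e.g. utm_project(zone)) ",
         "to reach a metric CRS before analysis")
  if (any(types %in% c("Polygon", "MultiPolygon"))) {
    patches <- list()
    for (k in seq_along(geoms)) {
      g <- geoms[[k]]
      id <- feats[[k]]$properties$id
      polys <- if (identical(g$type, "Polygon")) list(g$coordinates)
               else if (identical(g$type, "MultiPolygon")) g$coordinates
               else next
      for (pc in polys) {
        rings <- lapply(pc, .coords_to_matrix)
        rings <- lapply(rings, tr)
        patches[[length(patches) + 1L]] <-
          patch_polygon(rings[[1L]], holes = rings[-1L],
                        id = id %||% sprintf("f%03d", length(patches) + 1L))
      }
    }
    props <- gj$properties %||% list()
    patch_layer(patches,
                epoch = epoch %||% props$epoch %||% NA,
                crs = crs %||% props$crs %||% "local-metric",
                name = name %||% props$name %||% basename(path))
  } else if (any(types %in% c("LineString", "MultiLineString"))) {
    lines <- list()
    for (g in geoms) {
      if (identical(g$type, "LineString"))
        lines[[length(lines) + 1L]] <- tr(.coords_to_matrix(g$coordinates))
      else if (identical(g$type, "MultiLineString"))
        for (cc in g$coordinates)
          lines[[length(lines) + 1L]] <- tr(.coords_to_matrix(cc))
    }
    coastline_layer(lines)
  } else stop("format error: no Polygon or LineString features found")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.maybe_project <- function(m, project) {
  if (!is.null(project)) return(project(m))
  m
}

.is_geographic_crs <- function(crs) {
  !is.null(crs) && is.character(crs) &&
    grepl("4326|WGS\\s*84|CRS84|longlat", crs, ignore.case = TRUE)
}

# --------------------------------------------------------------------------
# WKT
# --------------------------------------------------------------------------

#' Write a patch layer as WKT
#'
#' One `POLYGON (...)` per line.
#' @param layer a `patch_layer`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wkt <- function(layer, path) {
  stopifnot(inherits(layer, "patch_layer"))
  fmt_ring <- function(m) {
    mm <- .close_ring(m)
    paste0("(", paste(sprintf("%.6f %.6f", mm[, 1L], mm[, 2L]),
                      collapse = ", "), ")")
  }
  lines <- vapply(layer$patches, function(p)
    paste0("POLYGON (", paste(vapply(.rings(p), fmt_ring, ""),
                              collapse = ", "), ")"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read WKT polygons
#'
#' Accepts `POLYGON` and `MULTIPOLYGON` geometries, one per line.
#' @param path file path.
#' @param project optional projection function as in [read_geojson()].
#' @inheritParams read_geojson
#' @return a `patch_layer`.
#' @export
read_wkt <- function(path, project = NULL, epoch = NA, crs = "local-metric",
                     name = basename(path)) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt[nzchar(trimws(txt))])
  patches <- list()
  for (line in txt) {
    u <- toupper(line)
    if (!startsWith(u, "POLYGON") && !startsWith(u, "MULTIPOLYGON"))
      stop("format error: unsupported WKT geometry: ", substr(line, 1, 20))
    body <- sub("^[A-Z]+\\s*", "", u)
    polys <- if (startsWith(u, "MULTIPOLYGON")) {
      inner <- sub("^\\(\\s*", "", sub("\\s*\\)$", "", body))
      strsplit(inner, "\\)\\s*\\)\\s*,\\s*\\(\\s*\\(")[[1L]]
    } else sub("^\\(\\s*", "", sub("\\s*\\)$", "", body))
    for (pb in polys) {
      pb <- gsub("^\\(+|\\)+$", "", pb)
      ringtxt <- strsplit(pb, "\\)\\s*,\\s*\\(")[[1L]]
      rings <- lapply(ringtxt, function(r) {
        r <- gsub("[()]", "", r)
        xy <- strsplit(trimws(strsplit(r, ",")[[1L]]), "\\s+")
        m <- do.call(rbind, lapply(xy, function(v) as.numeric(v[1:2])))
        .maybe_project(m, project)
      })
      patches[[length(patches) + 1L]] <-
        patch_polygon(rings[[1L]], holes = rings[-1L],
                      id = sprintf("w%03d", length(patches) + 1L))
    }
  }
  patch_layer(patches, epoch = epoch, crs = crs, name = name)
}

# --------------------------------------------------------------------------
# KML (optional backend)
# --------------------------------------------------------------------------

#' Read polygons from a KML file
#'
#' Requires the `xml2` package. KML stores lon/lat, so a projection
#' function is mandatory.
#' @param path KML file path.
#' @param project function projecting lon/lat to metric x/y, e.g.
#'   `utm_project(15, south = TRUE)`.
#' @inheritParams read_geojson
#' @return a `patch_layer`.
#' @export
read_kml <- function(path, project, epoch = NA, crs = "user-projected",
                     name = basename(path)) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("KML support needs the 'xml2' package; convert to GeoJSON instead")
  if (missing(project) || is.null(project))
    stop("CRS error: KML is geographic (lon/lat); a `project` function is required")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  polys <- xml2::xml_find_all(doc, ".//Polygon")
  parse_coords <- function(node) {
    txt <- xml2::xml_text(xml2::xml_find_first(node, ".//coordinates"))
    triplets <- strsplit(trimws(strsplit(trimws(txt), "\\s+")[[1L]]), ",")
    do.call(rbind, lapply(triplets, function(v) as.numeric(v[1:2])))
  }
  patches <- list()
  for (pg in polys) {
    ext <- parse_coords(xml2::xml_find_first(pg, ".//outerBoundaryIs"))
    holes <- lapply(xml2::xml_find_all(pg, ".//innerBoundaryIs"), parse_coords)
    patches[[length(patches) + 1L]] <-
      patch_polygon(project(ext), holes = lapply(holes, project),
                    id = sprintf("k%03d", length(patches) + 1L))
  }
  patch_layer(patches, epoch = epoch, crs = crs, name = name)
}

# --------------------------------------------------------------------------
# Transverse Mercator / UTM projection (WGS84)
# --------------------------------------------------------------------------

#' UTM projection function factory (WGS84)
#'
#' Returns a function mapping an n x 2 lon/lat matrix (degrees) to UTM
#' easting/northing in metres, using the standard transverse-Mercator
#' series (central scale 0.9996, false easting 500 km, false northing
#' 10 000 km in the southern hemisphere).
#' @param zone UTM zone number (1-60).
#' @param south southern-hemisphere zone (adds the false northing).
#' @return function `(matrix) -> matrix`.
#' @export
utm_project <- function(zone, south = TRUE) {
  stopifnot(zone >= 1, zone <= 60)
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (zone * 6 - 183) * pi / 180
  function(m) {
    m <- as.matrix(m)
    lon <- m[, 1L] * pi / 180; lat <- m[, 2L] * pi / 180
    N <- a / sqrt(1 - e2 * sin(lat)^2)
    T <- tan(lat)^2
    C <- ep2 * cos(lat)^2
    A <- (lon - lon0) * cos(lat)
    # meridian arc (series in e2)
    M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * lat -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * lat) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * lat) -
              (35 * e2^3 / 3072) * sin(6 * lat))
    x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                   (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 5e5
    y <- k0 * (M + N * tan(lat) * (A^2 / 2 +
               (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
               (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
    if (south) y <- y + 1e7
    cbind(x, y)
  }
}

# --------------------------------------------------------------------------
# ESRI ASCII grid raster
# --------------------------------------------------------------------------

#' Write one band as an ESRI ASCII grid
#'
#' @param band numeric matrix (north-up, row 1 = top).
#' @param origin,res georeference as in [spectral_scene()].
#' @param path output `.asc` path.
#' @param nodata no-data sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(band, origin, res, path, nodata = -9999) {
  nr <- nrow(band); nc <- ncol(band)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.6f", origin[1L]),
           sprintf("yllcorner %.6f", origin[2L] - nr * res),
           sprintf("cellsize %.6f", res),
           sprintf("NODATA_value %g", nodata))
  body <- apply(band, 1L, function(v) {
    v[is.na(v)] <- nodata
    paste(format(v, trim = TRUE, scientific = FALSE), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @return list with `band` (matrix, `NA` for no-data), `origin`
#'   `(x0, ytop)` and `res`, ready for [spectral_scene()].
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("format error: incomplete ASCII grid header")
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("format error: cell count does not match header")
  band <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) band[band == hdr$nodata_value] <- NA
  list(band = band,
       origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
       res = hdr$cellsize)
}

#' Read a multi-band scene from ASCII grids
#'
#' @param paths named character vector of `.asc` paths (names become
#'   band names, e.g. `c(R = "r.asc", NIR = "nir.asc")`).
#' @return a `spectral_scene`.
#' @export
read_scene_asc <- function(paths) {
  stopifnot(!is.null(names(paths)))
  gb <- lapply(paths, read_asc)
  b1 <- gb[[1L]]
  bands <- lapply(gb, `[[`, "band")
  nodata <- Reduce(`|`, lapply(bands, is.na))
  bands <- lapply(bands, function(m) { m[is.na(m)] <- 0; m })
  spectral_scene(bands, origin = b1$origin, res = b1$res, nodata = nodata)
}

# --------------------------------------------------------------------------
# Reports
# --------------------------------------------------------------------------

#' Write a JSON analysis report
#'
#' @param results named list of per-stage outputs (must be JSON
#'   serializable; data frames become arrays of records).
#' @param path output `.json` path.
#' @param config optional configuration echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  payload <- list(
    tool = "mangrovedyn",
    version = as.character(utils::packageVersion("mangrovedyn")),
    config = config,
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#' @param path report path.
#' @return the parsed report list.
#' @export
read_report <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)
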