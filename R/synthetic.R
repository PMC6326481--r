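# Seeded generator of synthetic coastal landscapes: a smoothed random-
# walk coastline, fringing star-shaped mangrove patches whose sizes
# follow a truncated log-normal (most patches < 0.5 ha) and whose
# anchor depths follow an exponential fringe law (~90% of cover within
# 500 m of shore), a scripted two-epoch change ledger, a multispectral
# scene with class-labelled training regions, and ground-truth points.
# Every random draw flows from the single script seed, so identical
# scripts give identical landscapes.

#' Default spectral signatures of the five tonality classes
#'
#' Band means (reflectance-like, 0-1) and per-band noise SD for the
#' five visually distinct cover classes: mangrove (dark lush green,
#' high NIR), deciduous vegetation (paler green/brown, medium NIR),
#' lava (dark grey, flat spectrum), sand (bright), water (dark, very
#' low NIR).
#' @return data frame with columns `class`, `R`, `G`, `B`, `NIR`, `sd`.
#' @export
default_spectra <- function() {
  data.frame(
    class = c("mangrove", "vegetation", "lava", "sand", "water"),
    R   = c(0.10, 0.34, 0.13, 0.75, 0.06),
    G   = c(0.30, 0.40, 0.11, 0.72, 0.12),
    B   = c(0.08, 0.20, 0.10, 0.60, 0.20),
    NIR = c(0.55, 0.42, 0.12, 0.50, 0.03),
    sd  = c(0.050, 0.050, 0.020, 0.020, 0.010),
    stringsAsFactors = FALSE)
}

#' Build a landscape script
#'
#' Bundles every generator parameter with the seed. Defaults encode the
#' fringing-mangrove statistics the generator emulates: log-normal
#' patch sizes (meanlog `log(1000)` m2, sdlog 1.56, so ~85% of patches
#' are below 0.5 ha), exponential anchor depth with 100 m mean (so
#' about half the cover sits within 100 m and ~90% within 500 m of the
#' shore), and a change mix of
#' 60% stable / 30% expanding (+80% area) / 8% contracting (-30%) /
#' 2% disappearing patches plus 5% newly generated ones, netting the
#' ~+24% decadal cover increase typical of an expanding fringe.
#'
#' @param seed integer RNG seed.
#' @param n_patches number of epoch-t patches.
#' @param coast_length coastline length in metres (default scales with
#'   `n_patches` to keep patch spacing realistic).
#' @param coast_step,coast_amp coastline vertex spacing and roughness
#'   amplitude (metres).
#' @param size_meanlog,size_sdlog,size_range log-normal patch-size
#'   parameters (m2) and truncation range.
#' @param fringe_mean,fringe_max exponential mean and truncation of the
#'   patch anchor depth from the coastline (metres).
#' @param patch_vertices,patch_rough star-polygon vertex count and
#'   relative radial roughness (0 = smooth circle-like patches).
#' @param min_gap minimum clearance kept between patches (metres);
#'   must exceed the STAMP threshold so planted events never merge.
#' @param change list of change-script probabilities and magnitudes:
#'   `p_stable`, `p_expand`, `p_contract`, `p_disappear` (summing to
#'   1), `expand_growth`, `contract_loss` (relative area change) and
#'   `gen_frac` (new patches as a fraction of `n_patches`).
#' @param spectra spectral signature table as [default_spectra()].
#' @param scene list of scene parameters: `res` (pixel size, m),
#'   `span` (along-shore window, m), `sea_margin`, `land_depth` (m),
#'   `sand_width`, `ring_width` (m), `veg_frac` (deciduous share of
#'   remaining land), `n_train`, `n_truth`.
#' @return an object of class `landscape_script`.
#' @export
landscape_script <- function(seed = 1, n_patches = 250,
                             coast_length = n_patches * 150,
                             coast_step = 50, coast_amp = 120,
                             size_meanlog = log(1000), size_sdlog = 1.56,
                             size_range = c(25, 5e4),
                             fringe_mean = 100, fringe_max = 700,
                             patch_vertices = 16, patch_rough = 0.35,
                             min_gap = 40,
                             change = list(), spectra = default_spectra(),
                             scene = list()) {
  ch <- modifyList(list(p_stable = 0.60, p_expand = 0.30, p_contract = 0.08,
                        p_disappear = 0.02, expand_growth = 0.8,
                        contract_loss = 0.3, gen_frac = 0.05), change)
  pr <- c(ch$p_stable, ch$p_expand, ch$p_contract, ch$p_disappear)
  if (abs(sum(pr) - 1) > 1e-9) stop("change probabilities must sum to 1")
  sc <- modifyList(list(res = 3, span = 1200, sea_margin = 250,
                        land_depth = 750, sand_width = 20, ring_width = 18,
                        veg_frac = 0.25, n_train = 300, n_truth = 500),
                   scene)
  if (fringe_max <= 0 || coast_length <= 0 || n_patches < 1)
    stop("infeasible script: patches cannot be placed on this coast")
  structure(list(seed = seed, n_patches = n_patches,
                 coast_length = coast_length, coast_step = coast_step,
                 coast_amp = coast_amp, size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog, size_range = size_range,
                 fringe_mean = fringe_mean, fringe_max = fringe_max,
                 patch_vertices = patch_vertices, patch_rough = patch_rough,
                 min_gap = min_gap, change = ch, spectra = spectra,
                 scene = sc),
            class = "landscape_script")
}

#' Sample patch sizes from a script's size law
#'
#' Truncated log-normal draw used for patch target areas; exposed so
#' the size distribution can be checked independently of placement.
#' @param n number of sizes.
#' @param script a `landscape_script`.
#' @return numeric vector of areas in square metres.
#' @export
sample_patch_sizes <- function(n, script) {
  out <- numeric(0)
  while (length(out) < n) {
    s <- rlnorm(n, script$size_meanlog, script$size_sdlog)
    s <- s[s >= script$size_range[1L] & s <= script$size_range[2L]]
    out <- c(out, s)
  }
  out[seq_len(n)]
}

.make_coastline <- function(script) {
  x <- seq(0, script$coast_length, by = script$coast_step)
  n <- length(x)
  w <- cumsum(rnorm(n, 0, script$coast_amp / sqrt(n) * 4))
  k <- 9
  y <- as.numeric(stats::filter(c(rep(w[1L], k), w, rep(w[n], k)),
                                rep(1 / (2 * k + 1), 2 * k + 1)))
  y <- y[(k + 1):(k + n)]
  y[is.na(y)] <- w[is.na(y)]
  y <- y - mean(y)
  cbind(x = x, y = y)
}

.coast_y <- function(coast, x) {
  stats::approx(coast[, 1L], coast[, 2L], xout = x, rule = 2)$y
}

.star_patch <- function(center, target_area, k, rough, id = NULL) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] +
    runif(1, 0, 2 * pi / k)
  r0 <- sqrt(target_area / pi)
  r <- r0 * (1 + rough * runif(k, -1, 1))
  m <- cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  p <- patch_polygon(m, id = id, check = FALSE)
  scale_patch(p, sqrt(target_area / area(p)), centre = center)
}

# Place n patches along the coast with guaranteed clearance even after
# the largest scripted expansion. Returns centers, radii and sizes.
.place_patches <- function(n, script, coast, occupied = NULL) {
  smax <- sqrt(1 + script$change$expand_growth)
  eff_factor <- (1 + script$patch_rough) * smax
  cx <- if (is.null(occupied)) numeric(0) else occupied$x
  cy <- if (is.null(occupied)) numeric(0) else occupied$y
  ce <- if (is.null(occupied)) numeric(0) else occupied$eff
  out <- vector("list", n)
  for (i in seq_len(n)) {
    size <- sample_patch_sizes(1L, script)
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (try %% 80L == 0L) size <- sample_patch_sizes(1L, script)
      x <- runif(1, 0, script$coast_length)
      d <- rexp(1, 1 / script$fringe_mean)
      if (d > script$fringe_max) next
      y <- .coast_y(coast, x) - d
      eff <- sqrt(size / pi) * eff_factor
      if (length(cx)) {
        dd <- sqrt((cx - x)^2 + (cy - y)^2) - (ce + eff)
        if (min(dd) < script$min_gap) next
      }
      cx <- c(cx, x); cy <- c(cy, y); ce <- c(ce, eff)
      out[[i]] <- c(x = x, y = y, size = size, depth = d)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible script: could not place patches with the required clearance")
  }
  as.data.frame(do.call(rbind, out))
}

#' Generate a synthetic coastal landscape
#'
#' Runs the full script: coastline, epoch-t patch layer, scripted
#' change into the epoch-t1 layer, the exact change ledger, and (unless
#' `scene = FALSE`) a multispectral scene consistent with the t1 layer,
#' training regions and labelled ground-truth points.
#' @param script a `landscape_script`.
#' @param scene build the raster scene (set `FALSE` for large vector-
#'   only landscapes).
#' @return list with elements `coastline` (`coastline_layer`),
#'   `layer_t`, `layer_t1` (`patch_layer`), `ledger` (data frame with
#'   one row per patch/event and exact planted areas), `script`, and —
#'   with a scene — `scene` (`spectral_scene`), `truth` (class-label
#'   matrix), `training` (`training_set`), `truth_points` (data frame
#'   `x`, `y`, `truth`).
#' @export
generate_landscape <- function(script, scene = TRUE) {
  stopifnot(inherits(script, "landscape_script"))
  set.seed(script$seed)
  coast <- .make_coastline(script)
  pl <- .place_patches(script$n_patches, script, coast)
  n <- nrow(pl)
  patches_t <- lapply(seq_len(n), function(i)
    .star_patch(c(pl$x[i], pl$y[i]), pl$size[i], script$patch_vertices,
                script$patch_rough, id = sprintf("p%04d", i)))
  ch <- script$change
  ev <- sample(c("stable", "expand", "contract", "disappear"), n,
               replace = TRUE,
               prob = c(ch$p_stable, ch$p_expand, ch$p_contract,
                        ch$p_disappear))
  patches_t1 <- list()
  led <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patches_t[[i]]
    a <- area(p)
    ctr <- c(pl$x[i], pl$y[i])
    if (ev[i] == "stable") {
      patches_t1[[length(patches_t1) + 1L]] <- p
      led[[i]] <- data.frame(id = p$id, event = "stable", area_t = a,
                             area_t1 = a, stb = a, expa = 0, con = 0,
                             gen = 0, dis = 0)
    } else if (ev[i] == "expand") {
      q <- scale_patch(p, sqrt(1 + ch$expand_growth), centre = ctr)
      a1 <- area(q)
      patches_t1[[length(patches_t1) + 1L]] <- q
      led[[i]] <- data.frame(id = p$id, event = "expand", area_t = a,
                             area_t1 = a1, stb = a, expa = a1 - a, con = 0,
                             gen = 0, dis = 0)
    } else if (ev[i] == "contract") {
      q <- scale_patch(p, sqrt(1 - ch$contract_loss), centre = ctr)
      a1 <- area(q)
      patches_t1[[length(patches_t1) + 1L]] <- q
      led[[i]] <- data.frame(id = p$id, event = "contract", area_t = a,
                             area_t1 = a1, stb = a1, expa = 0, con = a - a1,
                             gen = 0, dis = 0)
    } else {
      led[[i]] <- data.frame(id = p$id, event = "disappear", area_t = a,
                             area_t1 = 0, stb = 0, expa = 0, con = 0,
                             gen = 0, dis = a)
    }
  }
  n_gen <- round(ch$gen_frac * n)
  if (n_gen > 0) {
    occ <- data.frame(x = pl$x, y = pl$y,
                      eff = sqrt(pl$size / pi) *
                        (1 + script$patch_rough) *
                        sqrt(1 + ch$expand_growth))
    pg <- .place_patches(n_gen, script, coast, occupied = occ)
    for (i in seq_len(n_gen)) {
      q <- .star_patch(c(pg$x[i], pg$y[i]), pg$size[i],
                       script$patch_vertices, script$patch_rough,
                       id = sprintf("g%04d", i))
      patches_t1[[length(patches_t1) + 1L]] <- q
      led[[n + i]] <- data.frame(id = q$id, event = "generate", area_t = 0,
                                 area_t1 = area(q), stb = 0, expa = 0,
                                 con = 0, gen = area(q), dis = 0)
    }
  }
  ledger <- do.call(rbind, led)
  out <- list(
    coastline = coastline_layer(coast),
    layer_t = patch_layer(patches_t, epoch = 2004, crs = "synthetic-metric",
                          name = "epoch-t"),
    layer_t1 = patch_layer(patches_t1, epoch = 2014, crs = "synthetic-metric",
                           name = "epoch-t1"),
    ledger = ledger, script = script)
  if (scene) out <- c(out, .build_scene(script, coast, out$layer_t1))
  out
}

.smooth_field <- function(nr, nc, k = 11) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  w <- rep(1 / k, k)
  f <- apply(f, 2L, function(v) {
    s <- stats::filter(v, w, circular = TRUE)
    as.numeric(s)
  })
  f <- t(apply(f, 1L, function(v) as.numeric(stats::filter(v, w, circular = TRUE))))
  f
}

# Rasterize classes and draw band values for a window of the landscape.
.build_scene <- function(script, coast, layer, confusable = FALSE,
                         overlap = 0, algae_frac = 0.08) {
  sc <- script$scene
  xw <- c(0, min(sc$span, script$coast_length))
  cy <- .coast_y(coast, seq(xw[1L], xw[2L], by = script$coast_step))
  ytop <- max(cy) + sc$sea_margin
  ybot <- min(cy) - sc$land_depth
  res <- sc$res
  nc <- ceiling(diff(xw) / res)
  nr <- ceiling((ytop - ybot) / res)
  origin <- c(xw[1L], ytop)
  scn0 <- spectral_scene(list(R = matrix(0, nr, nc)), origin, res)
  ctr <- pixel_centers(scn0)
  coastY <- .coast_y(coast, ctr[, 1L])
  sea <- ctr[, 2L] > coastY
  # only patches reaching into the scene window matter for rasterization
  pad <- sc$ring_width + res
  inwin <- vapply(layer$patches, function(p) {
    b <- .bbox(p)
    b[3L] >= xw[1L] - pad && b[1L] <= xw[2L] + pad &&
      b[4L] >= ybot - pad && b[2L] <= ytop + pad
  }, TRUE)
  layer <- patch_layer(layer$patches[inwin], epoch = layer$epoch,
                       crs = layer$crs, name = layer$name)
  mang <- points_in_layer(ctr, layer)
  dshore <- abs(ctr[, 2L] - coastY)
  cls <- rep("lava", nr * nc)
  cls[sea] <- "water"
  # deciduous scatter on land + a deciduous collar hugging every patch
  fld <- .smooth_field(nr, nc)
  land_bg <- !sea & !mang
  qv <- quantile(fld[land_bg], 1 - sc$veg_frac, names = FALSE)
  cls[land_bg & as.vector(fld) >= qv] <- "vegetation"
  near <- distance_to_layer(ctr[land_bg, , drop = FALSE], layer)
  idx_bg <- which(land_bg)
  cls[idx_bg[near <= sc$ring_width]] <- "vegetation"
  cls[land_bg & cls == "lava" & dshore <= sc$sand_width] <- "sand"
  cls[mang] <- "mangrove"
  truthcls <- cls
  if (confusable) {
    fld2 <- .smooth_field(nr, nc)
    qa <- quantile(fld2[sea], 1 - algae_frac / mean(sea), names = FALSE)
    alg <- sea & !mang & as.vector(fld2) >= qa
    cls[alg] <- "algae"
    truthcls[alg] <- "algae"
  }
  spec <- script$spectra
  if (confusable && overlap > 0) {
    # pull the deciduous signature towards mangrove
    i_m <- which(spec$class == "mangrove"); i_v <- which(spec$class == "vegetation")
    for (b in c("R", "G", "B", "NIR"))
      spec[i_v, b] <- spec[i_m, b] + (1 - overlap) * (spec[i_v, b] - spec[i_m, b])
  }
  if (confusable) {
    alg_row <- spec[spec$class == "mangrove", ]
    alg_row$class <- "algae"
    spec <- rbind(spec, alg_row)
  }
  bands <- c("R", "G", "B", "NIR")
  bm <- lapply(bands, function(b) {
    v <- numeric(nr * nc)
    for (k in seq_len(nrow(spec))) {
      at <- cls == spec$class[k]
      v[at] <- spec[[b]][k] + rnorm(sum(at), 0, spec$sd[k])
    }
    matrix(v, nr, nc)
  })
  names(bm) <- bands
  scene <- spectral_scene(bm, origin, res)
  truth <- matrix(truthcls, nr, nc)
  # training regions drawn from the non-confusable truth classes
  train_classes <- c("mangrove", "vegetation", "lava", "sand", "water")
  regions <- lapply(train_classes, function(k) {
    idx <- which(truth == k)
    if (length(idx) > sc$n_train) idx <- sample(idx, sc$n_train)
    idx
  })
  names(regions) <- train_classes
  regions <- regions[vapply(regions, length, 0L) >= length(bands) + 1L]
  training <- training_from_regions(scene, regions)
  # labelled ground-truth points from the vector layer
  tp <- cbind(runif(sc$n_truth, xw[1L], xw[2L]), runif(sc$n_truth, ybot, ytop))
  truth_points <- data.frame(
    x = tp[, 1L], y = tp[, 2L],
    truth = ifelse(points_in_layer(tp, layer), "mangrove", "non-mangrove"),
    stringsAsFactors = FALSE)
  list(scene = scene, truth = truth, training = training,
       training_regions = regions, truth_points = truth_points)
}

#' Generate a confusable classification benchmark scene
#'
#' A compact landscape engineered to reproduce the failure modes of
#' RGB-based classification: the deciduous-vegetation signature is
#' pulled towards mangrove (controlled by `overlap`), and sea-surface
#' algae sharing the mangrove spectrum is planted on the sea side, so a
#' land/sea-partitioned classifier provably outperforms the whole-scene
#' one.
#' @param script a `landscape_script` (defaults to a dense 1.5 km
#'   benchmark stretch).
#' @param overlap in \[0, 1): 0 keeps the classes fully separable, values
#'   towards 1 collapse deciduous onto mangrove.
#' @param algae_frac fraction of the scene covered by sea-surface algae.
#' @return list with `scene`, `truth` (class matrix, `"algae"` marked
#'   explicitly), `truth_mangrove` (logical matrix), `training`
#'   (land+sea classes), `coastline`, `layer`, `land` (land/sea logical
#'   matrix), `script`.
#' @export
generate_confusable_scene <- function(script = NULL, overlap = 0.8,
                                      algae_frac = 0.08) {
  if (is.null(script))
    script <- landscape_script(seed = 1, n_patches = 18, coast_length = 1600,
                               coast_amp = 60,
                               size_meanlog = log(2500), size_sdlog = 0.8,
                               fringe_mean = 100, fringe_max = 350,
                               min_gap = 25,
                               scene = list(span = 1600, land_depth = 500,
                                            sea_margin = 250, res = 3))
  stopifnot(overlap >= 0, overlap < 1)
  set.seed(script$seed)
  coast <- .make_coastline(script)
  pl <- .place_patches(script$n_patches, script, coast)
  patches <- lapply(seq_len(nrow(pl)), function(i)
    .star_patch(c(pl$x[i], pl$y[i]), pl$size[i], script$patch_vertices,
                script$patch_rough, id = sprintf("p%04d", i)))
  layer <- patch_layer(patches, epoch = 2014, crs = "synthetic-metric",
                       name = "benchmark")
  parts <- .build_scene(script, coast, layer, confusable = TRUE,
                        overlap = overlap, algae_frac = algae_frac)
  cl <- coastline_layer(coast)
  land <- land_sea_mask(parts$scene, cl,
                        land_point = c(mean(range(coast[, 1L])),
                                       min(coast[, 2L]) - script$scene$land_depth / 2))
  c(parts, list(truth_mangrove = parts$truth == "mangrove",
                coastline = cl, layer = layer, land = land, script = script))
}

#' Run the three classification chains on a benchmark scene
#'
#' Convenience wrapper fitting the class models and producing the MLC1,
#' MLC2 and HYBRID mangrove maps plus their pixel accuracies against
#' the generating truth (mangrove vs non-mangrove).
#' @param bench output of [generate_confusable_scene()].
#' @param diff_threshold,min_size_px region-growing parameters; the
#'   default minimum segment size is scaled to the benchmark scene
#'   (the operational value of 750 px presumes full-resolution tiles).
#' @return list with logical mangrove grids `mlc1`, `mlc2`, `hybrid`
#'   and an `accuracy` named vector (percent) including the on-screen
#'   `reference` (truth itself).
#' @export
classification_benchmark <- function(bench, diff_threshold = 0.75,
                                     min_size_px = NULL) {
  scene <- bench$scene
  truth_m <- bench$truth_mangrove
  training <- bench$training
  land_classes <- c("mangrove", "vegetation", "lava", "sand")
  sea_classes <- "water"
  model_all <- mlc_train(training)
  model_land <- mlc_train(training[names(training) %in% land_classes])
  model_sea <- mlc_train(training[names(training) %in% sea_classes])
  lab1 <- mlc_classify(scene, model_all)
  lab2 <- mlc_classify_partitioned(scene, model_land, model_sea, bench$land)
  veg <- vegetation_mask(ndvi(scene))
  if (is.null(min_size_px)) min_size_px <- max(40L, round(sum(veg) / 60))
  seg <- region_grow_segment(scene, veg, diff_threshold, min_size_px)
  hyb <- hybrid_select(seg, lab2 == "mangrove" & !is.na(lab2))
  accpct <- function(m) 100 * mean(m == truth_m)
  list(mlc1 = lab1 == "mangrove" & !is.na(lab1),
       mlc2 = lab2 == "mangrove" & !is.na(lab2),
       hybrid = hyb,
       segments = seg,
       accuracy = c(reference = 100,
                    mlc2 = accpct(lab2 == "mangrove" & !is.na(lab2)),
                    mlc1 = accpct(lab1 == "mangrove" & !is.na(lab1)),
                    hybrid = accpct(hyb)))
}
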