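# NDVI, maximum-likelihood chains, region growing and raster tracing.

toy_scene <- function(nir, r, res = 1, origin = c(0, nrow(nir))) {
  spectral_scene(list(NIR = nir, R = r), origin = origin, res = res)
}

test_that("NDVI follows its arithmetic and bounds", {
  sc <- toy_scene(matrix(c(0.5, 0.8, 0, 0.2), 2, 2),
                  matrix(c(0.5, 0.2, 0.3, 0), 2, 2))
  v <- ndvi(sc)
  expect_equal(v[1, 1], 0)
  expect_equal(v[2, 1], 0.6)
  expect_equal(v[1, 2], -1)
  expect_equal(v[2, 2], 1)
  zero <- toy_scene(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(is.na(ndvi(zero))))
  no_nir <- spectral_scene(list(R = matrix(1, 2, 2)), c(0, 2), 1)
  expect_error(ndvi(no_nir), "missing band")
})

test_that("vegetation threshold is inclusive at 0.2", {
  g <- matrix(c(0.2, 0.19, -0.5, NA), 2, 2)
  m <- vegetation_mask(g)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("MLC fits class Gaussians and classifies by likelihood", {
  set.seed(2)
  tr <- structure(list(
    a = cbind(rnorm(50, 0, 0.05), rnorm(50, 0, 0.05)),
    b = cbind(rnorm(50, 1, 0.05), rnorm(50, 1, 0.05))), class = "training_set")
  colnames(tr$a) <- colnames(tr$b) <- c("R", "G")
  model <- mlc_train(tr)
  expect_equal(model$models$a$mean, colMeans(tr$a), ignore_attr = TRUE)
  sc <- spectral_scene(list(R = matrix(c(0, 1, 0.9, 0.1), 2, 2),
                            G = matrix(c(0, 1, 0.95, 0.05), 2, 2)),
                       c(0, 2), 1)
  lab <- mlc_classify(sc, model)
  expect_equal(as.vector(lab), c("a", "b", "b", "a"))
  expect_error(mlc_train(structure(list(a = tr$a[1:2, , drop = FALSE]),
                                   class = "training_set")),
               "insufficient")
})

test_that("duplicate training classes merge to the same model", {
  set.seed(3)
  px <- cbind(rnorm(60), rnorm(60)); colnames(px) <- c("R", "G")
  split_tr <- structure(list(a = px[1:30, ], a = px[31:60, ]),
                        class = "training_set")
  names(split_tr) <- c("a", "a")
  merged <- mlc_train(split_tr)
  direct <- mlc_train(structure(list(a = px), class = "training_set"))
  expect_equal(merged$models$a$mean, direct$models$a$mean)
  expect_equal(merged$models$a$chol, direct$models$a$chol)
})

test_that("well-separated classes are recovered at >= 99% and rescaling is harmless", {
  set.seed(4)
  means <- list(a = c(0.1, 0.2, 0.1), b = c(0.5, 0.6, 0.4),
                c = c(0.9, 0.2, 0.7), d = c(0.3, 0.9, 0.9))
  sdv <- 0.04  # >= 6 sigma separation by construction
  nr <- 60; nc <- 60
  truth <- matrix(sample(names(means), nr * nc, replace = TRUE), nr, nc)
  mk_band <- function(k) {
    v <- numeric(nr * nc)
    for (cl in names(means)) {
      at <- truth == cl
      v[at] <- means[[cl]][k] + rnorm(sum(at), 0, sdv)
    }
    matrix(v, nr, nc)
  }
  sc <- spectral_scene(list(R = mk_band(1), G = mk_band(2), B = mk_band(3)),
                       c(0, nr), 1)
  tr_idx <- lapply(setNames(names(means), names(means)),
                   function(cl) which(truth == cl)[1:40])
  model <- mlc_train(training_from_regions(sc, tr_idx))
  lab <- mlc_classify(sc, model)
  expect_gte(mean(lab == truth), 0.99)
  # band-wise affine rescaling applied to both training and scene
  sc2 <- sc
  sc2$bands <- lapply(sc$bands, function(b) 40 * b - 3)
  model2 <- mlc_train(training_from_regions(sc2, tr_idx))
  lab2 <- mlc_classify(sc2, model2)
  expect_identical(lab, lab2)
})

test_that("MLC matches an independent quadratic discriminant", {
  skip_if_not_installed("MASS")
  set.seed(6)
  n <- 80
  X <- rbind(cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.2)),
             cbind(rnorm(n, 1, 0.25), rnorm(n, 0.8, 0.35)))
  cls <- rep(c("a", "b"), each = n)
  tr <- structure(split.data.frame(X, cls), class = "training_set")
  tr <- lapply(tr, function(m) { colnames(m) <- c("R", "G"); m })
  class(tr) <- "training_set"
  model <- mlc_train(tr)
  grid <- as.matrix(expand.grid(seq(-0.5, 1.5, 0.1), seq(-0.5, 1.3, 0.1)))
  sc <- spectral_scene(list(R = matrix(grid[, 1], ncol = 1),
                            G = matrix(grid[, 2], ncol = 1)),
                       c(0, nrow(grid)), 1)
  mine <- as.vector(mlc_classify(sc, model))
  colnames(X) <- colnames(grid) <- c("R", "G")
  q <- MASS::qda(X, grouping = cls, prior = c(0.5, 0.5))
  ref <- as.character(predict(q, grid)$class)
  expect_gte(mean(mine == ref), 0.995)
})

test_that("land/sea mask follows the pixel-centre rule", {
  coast <- coastline_layer(cbind(c(-10, 110), c(50, 50)))
  sc <- spectral_scene(list(R = matrix(0, 10, 10)), c(0, 100), 10)
  land <- land_sea_mask(sc, coast, land_point = c(50, 0))
  expect_true(all(land[6:10, ]))   # rows below y = 50
  expect_false(any(land[1:5, ]))
})

test_that("region growing partitions the mask and respects spectral jumps", {
  b <- matrix(0, 20, 30); b[, 16:30] <- 1
  sc <- spectral_scene(list(R = b), c(0, 20), 1)
  mask <- matrix(TRUE, 20, 30)
  seg <- region_grow_segment(sc, mask, diff_threshold = 0.3, min_size_px = 5)
  expect_equal(length(unique(as.vector(seg))), 2L)
  expect_true(all(seg > 0))
  expect_equal(length(unique(as.vector(seg[, 1:15]))), 1L)
  # uniform image is one segment
  su <- region_grow_segment(spectral_scene(list(R = matrix(1, 10, 10)),
                                           c(0, 10), 1),
                            matrix(TRUE, 10, 10), 0.3, 5)
  expect_equal(unique(as.vector(su)), 1L)
  # planted speckle below the minimum size is absorbed
  b2 <- matrix(0, 30, 30); b2[14:16, 14:16] <- 0.6
  sp <- region_grow_segment(spectral_scene(list(R = b2), c(0, 30), 1),
                            matrix(TRUE, 30, 30), diff_threshold = 0.3,
                            min_size_px = 100)
  expect_equal(unique(as.vector(sp)), 1L)
  # empty mask
  se <- region_grow_segment(sc, matrix(FALSE, 20, 30), 0.3, 5)
  expect_true(all(se == 0))
})

test_that("hybrid selection takes whole segments on any overlap", {
  seg <- matrix(c(1, 1, 2, 2), 2, 2)
  none <- hybrid_select(seg, matrix(FALSE, 2, 2))
  expect_false(any(none))
  one_px <- hybrid_select(seg, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(as.vector(one_px), c(TRUE, TRUE, FALSE, FALSE))
  whole <- hybrid_select(seg, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_identical(as.vector(whole), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("raster conversion applies the 10 m2 MMU", {
  lab <- matrix("x", 10, 10)
  lab[2:4, 2:4] <- "m"            # 9 m2: erased
  lab[6:9, 6:8] <- "m"            # 12 m2: kept
  layer <- raster_to_patches(lab, "m", origin = c(0, 10), res = 1)
  expect_length(layer$patches, 1L)
  expect_equal(area(layer), 12)
  # checkerboard at 1 m: every isolated cell is below the MMU
  cb <- ifelse(outer(1:10, 1:10, "+") %% 2 == 0, "m", "x")
  expect_length(raster_to_patches(cb, "m", c(0, 10), 1)$patches, 0L)
})
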